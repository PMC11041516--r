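#' Overdose alert thresholds
#'
#' A sustained respiration rate below 8 bpm is the consulted-expert danger
#' threshold: the monitor alerts when the rate stays below it for 15 seconds
#' *or* for 2 full breaths (either condition suffices; the breath-count path
#' distinguishes a sustained slow rate from a momentary low reading), and
#' independently when no respiratory motion at all is seen for 10 seconds
#' (cessation), catching a decline too fast to track.
#'
#' @param rate_threshold bpm (default 8).
#' @param sustain_time seconds the sub-threshold rate must persist (15).
#' @param sustain_breaths consecutive slow breaths that also trigger (2);
#'   set `Inf` to disable the breath-count path.
#' @param cessation_time seconds of respiratory silence that trigger (10).
#' @export
alert_config <- function(rate_threshold = 8, sustain_time = 15,
                         sustain_breaths = 2, cessation_time = 10) {
  vals <- c(rate_threshold, sustain_time, sustain_breaths, cessation_time)
  if (any(!vals > 0)) stop_odr("invalid_spec", "alert thresholds must be positive")
  structure(list(rate_threshold = rate_threshold, sustain_time = sustain_time,
                 sustain_breaths = sustain_breaths,
                 cessation_time = cessation_time),
            class = "alert_config")
}

#' Fresh monitor state
#'
#' @return a `monitor_state` list: `mode` (normal / low_rate_pending /
#'   silent_pending / alerted), `condition_onset`, `slow_breath_count`,
#'   `slow_onset`, `silent_accum`, `last_now`.
#' @export
monitor_state <- function() {
  structure(list(mode = "normal", condition_onset = NA_real_,
                 slow_breath_count = 0L, slow_onset = NA_real_,
                 silent_accum = 0, last_now = NA_real_),
            class = "monitor_state")
}

#' Advance the overdose state machine by one observation
#'
#' Call once per rate-series tick with the current estimate, any breath
#' cycle completed since the previous tick, and whether a body-motion event
#' is in progress. Semantics:
#'
#' * low-rate, window path: the earliest time all valid estimates over the
#'   trailing `sustain_time` were below `rate_threshold`. Invalid estimates
#'   (tracking gaps) do not reset the window — a fading signal must not
#'   defeat both triggers — but a valid at-or-above-threshold estimate does.
#' * low-rate, breath-count path: `sustain_breaths` consecutive completed
#'   cycles each slower than `60 / rate_threshold`; a faster cycle resets
#'   the count.
#' * cessation: the silence clock accrues while neither a completed cycle
#'   nor sub-cycle respiratory movement (`breath_motion`) is observed;
#'   `motion_active` suspends (not resets) the clock, since a moving body is
#'   not a silent one.
#'
#' After an alert the state latches (`mode = "alerted"`) and no further
#' events are emitted until [alert_reset()].
#'
#' @param state a `monitor_state`.
#' @param now current time, s; must be non-decreasing across calls.
#' @param estimate a rate estimate as returned by [estimate_rate()].
#' @param new_cycle a single-row cycle data.frame completed since the last
#'   call, or `NULL`.
#' @param motion_active is a body-motion event (plus its blanking window) in
#'   progress?
#' @param cfg an [alert_config()].
#' @param breath_motion optional: was sub-cycle respiratory movement seen
#'   since the last call? (Computed by [monitor()] from the tracker's
#'   activity channel; when omitted only completed cycles feed the silence
#'   clock.)
#' @return list with `state` (updated) and `event` (an alert event list with
#'   `time`, `kind`, `triggering_rate`, `condition_duration`, or `NULL`).
#' @export
alert_step <- function(state, now, estimate, new_cycle = NULL,
                       motion_active = FALSE, cfg = alert_config(),
                       breath_motion = FALSE) {
  if (!is.na(state$last_now) && now < state$last_now - 1e-9) {
    stop_odr("monotonic_time", "time went backwards (%.3f after %.3f)",
             now, state$last_now)
  }
  dtv <- if (is.na(state$last_now)) 0 else now - state$last_now
  state$last_now <- now
  if (state$mode == "alerted") return(list(state = state, event = NULL))

  slow_period <- 60 / cfg$rate_threshold
  breath_seen <- FALSE

  if (!is.null(new_cycle) && nrow(new_cycle)) {
    breath_seen <- TRUE
    for (i in seq_len(nrow(new_cycle))) {
      if (new_cycle$period[i] > slow_period) {
        if (state$slow_breath_count == 0L) {
          state$slow_onset <- new_cycle$start_time[i]
        }
        state$slow_breath_count <- state$slow_breath_count + 1L
      } else {
        state$slow_breath_count <- 0L
        state$slow_onset <- NA_real_
      }
    }
  }

  if (isTRUE(estimate$valid)) {
    if (estimate$rate < cfg$rate_threshold) {
      if (is.na(state$condition_onset)) state$condition_onset <- now
    } else {
      state$condition_onset <- NA_real_
    }
  }

  if (motion_active) {
    # suspended: neither accrue nor reset
  } else if (breath_seen || isTRUE(breath_motion)) {
    state$silent_accum <- 0
  } else {
    state$silent_accum <- state$silent_accum + dtv
  }

  event <- NULL
  if (!is.na(state$condition_onset) &&
      now - state$condition_onset >= cfg$sustain_time - 1e-9) {
    event <- list(time = now, kind = "low_rate",
                  triggering_rate = if (isTRUE(estimate$valid)) estimate$rate else NA_real_,
                  condition_duration = now - state$condition_onset)
  } else if (is.finite(cfg$sustain_breaths) &&
             state$slow_breath_count >= cfg$sustain_breaths) {
    event <- list(time = now, kind = "low_rate",
                  triggering_rate = if (isTRUE(estimate$valid)) estimate$rate else NA_real_,
                  condition_duration = now - state$slow_onset)
  } else if (state$silent_accum >= cfg$cessation_time - 1e-9) {
    event <- list(time = now, kind = "cessation", triggering_rate = NA_real_,
                  condition_duration = state$silent_accum)
  }

  if (!is.null(event)) {
    state$mode <- "alerted"
  } else if (!is.na(state$condition_onset) || state$slow_breath_count > 0L) {
    state$mode <- "low_rate_pending"
  } else if (state$silent_accum > 0) {
    state$mode <- "silent_pending"
  } else {
    state$mode <- "normal"
  }
  list(state = state, event = event)
}

#' Re-arm a latched monitor
#' @param state a `monitor_state`.
#' @export
alert_reset <- function(state) {
  keep <- state$last_now
  state <- monitor_state()
  state$last_now <- keep
  state
}

#' Run the overdose monitor over a whole trace
#'
#' Tracks the trace ([track()]) and folds [alert_step()] over the rate
#' series, delivering each completed cycle at the first tick at or after its
#' end, marking ticks inside motion events (plus blanking) as
#' `motion_active`, and deriving `breath_motion` from the tracker's activity
#' channel.
#'
#' @param trace a [radar_trace()].
#' @param tcfg a [tracker_config()].
#' @param acfg an [alert_config()].
#' @return an `alert_log`: list with `events` (data.frame `time`, `kind`,
#'   `triggering_rate`, `condition_duration`) and the underlying `tracking`
#'   result.
#' @export
monitor <- function(trace, tcfg = tracker_config(), acfg = alert_config()) {
  tr <- track(trace, tcfg)
  fold_alerts(tr, acfg, tcfg)
}

fold_alerts <- function(tr, acfg, tcfg) {
  st <- monitor_state()
  events <- list()
  ticks <- tr$rate_series$time
  me <- tr$motion_events
  act <- tr$activity
  prev <- -Inf
  for (j in seq_along(ticks)) {
    now <- ticks[j]
    cyc_sel <- tr$cycles$end_time > prev + 1e-9 & tr$cycles$end_time <= now + 1e-9
    new_cycle <- if (any(cyc_sel)) tr$cycles[cyc_sel, , drop = FALSE] else NULL
    motion_active <- nrow(me) > 0 &&
      any(now >= me$start_time - 1e-9 &
          now <= me$end_time + tcfg$motion_blank_time + 1e-9)
    bm <- !is.null(act) &&
      any(act$active[act$time > prev + 1e-9 & act$time <= now + 1e-9])
    est <- list(time = now, rate = tr$rate_series$rate[j],
                valid = tr$rate_series$valid[j])
    out <- alert_step(st, now, est, new_cycle, motion_active, acfg, bm)
    st <- out$state
    if (!is.null(out$event)) events[[length(events) + 1L]] <- out$event
    prev <- now
  }
  ev <- if (length(events)) {
    do.call(rbind, lapply(events, function(e) {
      data.frame(time = e$time, kind = e$kind,
                 triggering_rate = e$triggering_rate,
                 condition_duration = e$condition_duration,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(time = numeric(0), kind = character(0),
               triggering_rate = numeric(0), condition_duration = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(list(events = ev, tracking = tr, state = st), class = "alert_log")
}

#' @export
print.alert_log <- function(x, ...) {
  if (!nrow(x$events)) {
    cat("<alert_log> no alerts\n")
  } else {
    cat(sprintf("<alert_log> %d event(s):\n", nrow(x$events)))
    print(x$events)
  }
  invisible(x)
}
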