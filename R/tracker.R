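#' Tracker configuration
#'
#' The tracker registers an exhale when chest distance increases and an
#' inhale when it decreases, and only counts a direction change as a breath
#' phase when its excursion lies inside the amplitude gate: at least
#' `min_excursion` (0.75 mm, noise immunity) and at most `max_excursion`
#' (20 mm); anything beyond 20 mm is treated as body motion, which opens a
#' motion event and forces a recalibration of the relative-distance tracking.
#'
#' @param min_excursion smallest breath excursion in mm (default 0.75). Also
#'   used as the reversal-commitment hysteresis: a direction change is
#'   committed only once the signal retraces this far from the candidate
#'   extremum.
#' @param max_excursion largest breath excursion in mm (default 20); larger
#'   swings are body motion.
#' @param smoothing_cutoff zero-phase low-pass cutoff in Hz applied by
#'   [preprocess()] (default 1 Hz: passes breathing up to 60 bpm, suppresses
#'   sensor noise).
#' @param motion_blank_time seconds the signal must stay inside the
#'   `max_excursion` band before tracking is considered re-stabilized after
#'   a motion event (default 2 s, the observed settling time after a slump).
#' @param sample_interval expected trace sampling interval, s.
#' @param staleness_horizon seconds after the last completed cycle for which
#'   a rate estimate is still considered valid (default 15 s).
#' @param rate_cadence spacing of the emitted rate series, s.
#' @param slope_threshold smoothed-derivative magnitude (mm/s) above which
#'   the chest is considered to be moving with breathing (cessation
#'   evidence); default 0.5 mm/s, ~5x the derivative noise floor at the
#'   default sensor noise.
#' @param slope_sigma Gaussian width (s) of the derivative smoother.
#' @param min_period shortest plausible breath period, s (default 1.5, i.e.
#'   40 bpm, twice the 20 bpm design maximum); faster reversal pairs are
#'   residual noise, not breaths, and are not emitted as cycles.
#' @export
tracker_config <- function(min_excursion = 0.75, max_excursion = 20,
                           smoothing_cutoff = 1.0, motion_blank_time = 2.0,
                           sample_interval = 0.05, staleness_horizon = 15,
                           rate_cadence = 0.5, slope_threshold = 0.5,
                           slope_sigma = 0.3, min_period = 1.5) {
  if (!(min_excursion > 0 && min_excursion < max_excursion)) {
    stop_odr("invalid_spec", "need 0 < min_excursion < max_excursion")
  }
  if (motion_blank_time < 0) stop_odr("invalid_spec", "motion_blank_time must be >= 0")
  structure(list(min_excursion = min_excursion, max_excursion = max_excursion,
                 smoothing_cutoff = smoothing_cutoff,
                 motion_blank_time = motion_blank_time,
                 sample_interval = sample_interval,
                 staleness_horizon = staleness_horizon,
                 rate_cadence = rate_cadence,
                 slope_threshold = slope_threshold,
                 slope_sigma = slope_sigma, min_period = min_period),
            class = "tracker_config")
}

#' Low-pass a trace without phase distortion
#'
#' Zero-phase windowed-sinc smoothing at `cfg$smoothing_cutoff`; length and
#' timebase are preserved, respiration-band content (<= 1 Hz) passes with
#' near-unity gain so peak locations are not displaced.
#'
#' @param trace an [radar_trace()] or [belt_trace()].
#' @param cfg a [tracker_config()].
#' @return a trace of the same class.
#' @export
preprocess <- function(trace, cfg = tracker_config()) {
  check_nonempty(trace)
  y <- fir_lowpass(trace$samples, trace$sample_interval, cfg$smoothing_cutoff)
  out <- trace
  out$samples <- y
  out
}

#' Segment a chest-distance trace into breath cycles
#'
#' Direction reversals are detected with hysteresis: a candidate extremum is
#' committed once the signal retraces at least `min_excursion` from it, so
#' every committed inhale/exhale phase has excursion within the amplitude
#' gate by construction. A cycle runs from one exhale-end (local distance
#' maximum) to the next, with the interior distance minimum as the inhale
#' peak. Any phase excursion beyond `max_excursion` opens a motion event:
#' the partial cycle is discarded, no cycles are emitted until the signal
#' has stayed inside a `max_excursion` band for `motion_blank_time`, and the
#' stabilized stretch is then replayed through a fresh tracker so breathing
#' resumed during the confirmation window is not lost.
#'
#' @param trace the (typically preprocessed) trace.
#' @param cfg a [tracker_config()]; `cfg$sample_interval` must match the
#'   trace.
#' @return a `tracking_result`: list with `cycles` (data.frame `start_time`,
#'   `end_time`, `inhale_peak_time`, `period`, `excursion`), `rate_series`
#'   (data.frame `time`, `rate`, `valid`) sampled every `cfg$rate_cadence`,
#'   and `motion_events` (data.frame `start_time`, `end_time`, `magnitude`).
#' @export
segment_breaths <- function(trace, cfg = tracker_config()) {
  check_nonempty(trace)
  if (abs(trace$sample_interval - cfg$sample_interval) > 1e-9) {
    stop_odr("config", "cfg$sample_interval (%g) does not match trace (%g)",
             cfg$sample_interval, trace$sample_interval)
  }
  core <- seg_core(trace_times(trace), trace$samples, cfg)
  cycles <- cycles_from_extrema(core$extrema, cfg)
  rate_times <- seq(trace$start_time,
                    trace$start_time + trace_duration(trace),
                    by = cfg$rate_cadence)
  rs <- do.call(rbind, lapply(rate_times, function(tt) {
    e <- estimate_rate(cycles, tt, staleness = cfg$staleness_horizon)
    data.frame(time = tt, rate = e$rate, valid = e$valid)
  }))
  structure(list(cycles = cycles, rate_series = rs,
                 motion_events = core$motion_events),
            class = "tracking_result")
}

#' @export
print.tracking_result <- function(x, ...) {
  cat(sprintf("<tracking_result> %d cycles, %d motion events, rate series n = %d\n",
              nrow(x$cycles), nrow(x$motion_events), nrow(x$rate_series)))
  invisible(x)
}

# Hysteresis extremum tracker with motion gating. Returns committed extrema
# (time, value, type in {"max","min"}) and motion events. Implemented as an
# explicit state machine over samples; motion recovery replays the buffered
# stabilization window through a reset tracker state.
seg_core <- function(tt, xx, cfg) {
  hyst <- cfg$min_excursion
  gate <- cfg$max_excursion
  n <- length(xx)

  ext_t <- numeric(0); ext_v <- numeric(0); ext_k <- character(0)
  mot <- list()

  # tracker state
  st <- new.env(parent = emptyenv())
  reset_state <- function(i) {
    st$dir <- 0L
    st$cmax_v <- xx[i]; st$cmax_t <- tt[i]
    st$cmin_v <- xx[i]; st$cmin_t <- tt[i]
    st$anchor_v <- xx[i]; st$anchor_t <- tt[i]
  }
  commit <- function(type, v, t) {
    ext_t <<- c(ext_t, t); ext_v <<- c(ext_v, v); ext_k <<- c(ext_k, type)
    st$anchor_v <- v; st$anchor_t <- t
  }

  mode <- "track"
  band_lo <- band_hi <- band_t0 <- NA_real_
  band_i0 <- NA_integer_
  mot_start <- NA_real_; mot_mag <- 0

  i <- 1L
  reset_state(1L)
  while (i <= n) {
    x <- xx[i]; t <- tt[i]
    if (mode == "motion") {
      band_lo <- min(band_lo, x); band_hi <- max(band_hi, x)
      mot_mag <- max(mot_mag, abs(x - st$anchor_v))
      if (band_hi - band_lo > gate) {
        band_lo <- band_hi <- x; band_t0 <- t; band_i0 <- i
      }
      if (t - band_t0 >= cfg$motion_blank_time) {
        mot[[length(mot) + 1L]] <- c(mot_start, band_t0, mot_mag)
        mode <- "track"
        reset_state(band_i0)
        i <- band_i0    # replay the stabilized stretch
        next
      }
      i <- i + 1L
      next
    }

    # track mode -------------------------------------------------------
    if (x > st$cmax_v) { st$cmax_v <- x; st$cmax_t <- t }
    if (x < st$cmin_v) { st$cmin_v <- x; st$cmin_t <- t }

    # body-motion gate: phase excursion from the last committed extremum
    if (abs(x - st$anchor_v) > gate) {
      mode <- "motion"
      # the step departs from the most recent reversal point
      mot_start <- if (st$dir == 1L) st$cmin_t
                   else if (st$dir == -1L) st$cmax_t
                   else st$anchor_t
      mot_mag <- abs(x - st$anchor_v)
      band_lo <- band_hi <- x; band_t0 <- t; band_i0 <- i
      # drop the partial cycle: forget uncommitted extrema
      i <- i + 1L
      next
    }

    if (st$dir == 0L) {
      if (x - st$cmin_v >= hyst) {
        commit("min", st$cmin_v, st$cmin_t)
        st$dir <- 1L; st$cmax_v <- x; st$cmax_t <- t
      } else if (st$cmax_v - x >= hyst) {
        commit("max", st$cmax_v, st$cmax_t)
        st$dir <- -1L; st$cmin_v <- x; st$cmin_t <- t
      }
    } else if (st$dir == 1L) {
      if (st$cmax_v - x >= hyst) {
        commit("max", st$cmax_v, st$cmax_t)
        st$dir <- -1L; st$cmin_v <- x; st$cmin_t <- t
      }
    } else {
      if (x - st$cmin_v >= hyst) {
        commit("min", st$cmin_v, st$cmin_t)
        st$dir <- 1L; st$cmax_v <- x; st$cmax_t <- t
      }
    }
    i <- i + 1L
  }

  # end-of-data flush: commit a pending candidate if the retrace got at
  # least halfway to the hysteresis bound (boundary policy; see vignette)
  if (mode == "track" && st$dir != 0L) {
    last_x <- xx[n]
    if (st$dir == 1L && st$cmax_v - last_x >= hyst / 2 &&
        st$cmax_t > st$anchor_t) {
      commit("max", st$cmax_v, st$cmax_t)
    } else if (st$dir == -1L && last_x - st$cmin_v >= hyst / 2 &&
               st$cmin_t > st$anchor_t) {
      commit("min", st$cmin_v, st$cmin_t)
    }
  }
  if (mode == "motion") {
    mot[[length(mot) + 1L]] <- c(mot_start, tt[n], mot_mag)
  }

  me <- if (length(mot)) {
    m <- do.call(rbind, mot)
    data.frame(start_time = m[, 1], end_time = m[, 2], magnitude = m[, 3])
  } else {
    data.frame(start_time = numeric(0), end_time = numeric(0),
               magnitude = numeric(0))
  }
  list(extrema = data.frame(time = ext_t, value = ext_v, type = ext_k,
                            stringsAsFactors = FALSE),
       motion_events = me)
}

# Build max -> min -> max cycles from the committed extrema sequence.
cycles_from_extrema <- function(ext, cfg) {
  empty <- data.frame(start_time = numeric(0), end_time = numeric(0),
                      inhale_peak_time = numeric(0), period = numeric(0),
                      excursion = numeric(0))
  if (nrow(ext) < 3) return(empty)
  rows <- list()
  imax <- which(ext$type == "max")
  for (j in seq_along(imax)[-1]) {
    a <- imax[j - 1L]; b <- imax[j]
    if (b - a != 2L || ext$type[a + 1L] != "min") next  # motion reset between
    if (ext$time[b] - ext$time[a] < cfg$min_period) next # too fast: noise
    drop1 <- ext$value[a] - ext$value[a + 1L]
    rise <- ext$value[b] - ext$value[a + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      start_time = ext$time[a], end_time = ext$time[b],
      inhale_peak_time = ext$time[a + 1L],
      period = ext$time[b] - ext$time[a],
      excursion = (drop1 + rise) / 2)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Current respiration rate from the cycle history
#'
#' The current rate is 60 / period of the most recent completed cycle at or
#' before `at_time`; once `staleness` seconds have passed with no completed
#' cycle the estimate is flagged invalid (tracking has gone silent).
#'
#' @param cycles cycles data.frame from [segment_breaths()].
#' @param at_time query time, s.
#' @param staleness staleness horizon in seconds (default 15).
#' @return list with `time`, `rate` (bpm, NA when invalid), `source_cycle`
#'   (row index or NA) and `valid`.
#' @export
estimate_rate <- function(cycles, at_time, staleness = 15) {
  invalid <- list(time = at_time, rate = NA_real_, source_cycle = NA_integer_,
                  valid = FALSE)
  if (is.null(cycles) || !nrow(cycles)) return(invalid)
  k <- which(cycles$end_time <= at_time + 1e-9)
  if (!length(k)) return(invalid)
  k <- k[length(k)]
  if (at_time - cycles$end_time[k] > staleness) return(invalid)
  list(time = at_time, rate = 60 / cycles$period[k], source_cycle = k,
       valid = TRUE)
}

#' Track a chest-distance trace end to end
#'
#' [preprocess()] then [segment_breaths()], plus a per-sample respiratory
#' activity channel: the smoothed derivative of the chest distance exceeds
#' `cfg$slope_threshold` wherever the chest is moving with breathing (used
#' by the cessation trigger as sub-cycle evidence of life). Samples inside
#' motion events (body motion, not breathing) are excluded from activity.
#'
#' @inheritParams segment_breaths
#' @return a `tracking_result` with an extra `activity` data.frame
#'   (`time`, `active`).
#' @export
track <- function(trace, cfg = tracker_config()) {
  filt <- preprocess(trace, cfg)
  res <- segment_breaths(filt, cfg)
  tt <- trace_times(filt)
  slope <- dog_slope(filt$samples, filt$sample_interval, cfg$slope_sigma)
  active <- abs(slope) >= cfg$slope_threshold
  me <- res$motion_events
  if (nrow(me)) {
    for (i in seq_len(nrow(me))) {
      active[tt >= me$start_time[i] &
             tt <= me$end_time[i] + cfg$motion_blank_time] <- FALSE
    }
  }
  res$activity <- data.frame(time = tt, active = active)
  res
}
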