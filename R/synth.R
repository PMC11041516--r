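#' Scenario segments for the breathing simulator
#'
#' A scenario is a piecewise description of what the chest does in front of
#' the sensor: quasi-periodic breathing at a programmed rate and
#' peak-to-trough excursion, breath-holds, apnea, and large slump-transition
#' motion artifacts. The simulator turns a scenario into a radar
#' chest-distance trace plus the ground truth needed to score the tracker.
#'
#' @param duration segment duration in seconds (> 0).
#' @param kind one of `"breathing"`, `"breath_hold"`, `"apnea"`,
#'   `"motion_transient"`.
#' @param rate breaths per minute (required > 0 for breathing segments).
#' @param amplitude peak-to-trough chest excursion in mm for breathing;
#'   for `motion_transient` segments it is reinterpreted as the baseline
#'   step magnitude (default 100 mm, well beyond the 20 mm body-motion gate).
#' @export
breathing_segment <- function(duration, kind = "breathing", rate = NA_real_,
                              amplitude = 0) {
  kinds <- c("breathing", "breath_hold", "apnea", "motion_transient")
  if (!kind %in% kinds) stop_odr("invalid_spec", "unknown segment kind '%s'", kind)
  if (!is.finite(duration) || duration <= 0) {
    stop_odr("invalid_spec", "segment duration must be positive")
  }
  if (kind == "breathing" && (!is.finite(rate) || rate <= 0)) {
    stop_odr("invalid_spec", "breathing segments need rate > 0 bpm")
  }
  if (is.finite(amplitude) && amplitude < 0) {
    stop_odr("invalid_spec", "amplitude must be >= 0")
  }
  if (kind %in% c("breath_hold", "apnea")) amplitude <- 0
  structure(list(duration = duration, kind = kind, rate = rate,
                 amplitude = amplitude),
            class = "breathing_segment")
}

#' Scenario specification
#'
#' @param segments list of [breathing_segment()]s, played back in order.
#' @param baseline_distance resting chest-to-sensor distance in mm
#'   (default 1000 mm, the middle of the 0.75-1.5 m operating band).
#' @param noise_sd additive white Gaussian sensor noise, mm (default 0.25).
#' @param drift_rate linear baseline drift, mm/s.
#' @param seed integer seed; identical specs (including seed) generate
#'   bit-identical traces.
#' @param sample_interval sampling interval, s (default 0.05 = 20 Hz, giving
#'   > 60 samples per cycle across the 4-20 bpm design range).
#' @param period_jitter_cv coefficient of variation of the per-cycle period
#'   jitter (default 0.05); set 0 for exactly periodic waveforms.
#' @param motion_ramp duration of the smooth baseline step inside a
#'   motion_transient segment, s.
#' @param motion_noise_sd extra noise during motion transients, mm
#'   (readjustment jitter while the body settles).
#' @export
scenario_spec <- function(segments, baseline_distance = 1000, noise_sd = 0.25,
                          drift_rate = 0, seed = 1L, sample_interval = 0.05,
                          period_jitter_cv = 0.05, motion_ramp = 1.5,
                          motion_noise_sd = 5) {
  if (inherits(segments, "breathing_segment")) segments <- list(segments)
  if (!length(segments) || !all(vapply(segments, inherits, TRUE, "breathing_segment"))) {
    stop_odr("invalid_spec", "segments must be a non-empty list of breathing_segment")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop_odr("invalid_spec", "noise_sd must be >= 0")
  }
  if (!is.finite(sample_interval) || sample_interval <= 0) {
    stop_odr("invalid_spec", "sample_interval must be positive")
  }
  structure(list(segments = segments, baseline_distance = baseline_distance,
                 noise_sd = noise_sd, drift_rate = drift_rate,
                 seed = as.integer(seed), sample_interval = sample_interval,
                 period_jitter_cv = period_jitter_cv,
                 motion_ramp = motion_ramp, motion_noise_sd = motion_noise_sd),
            class = "scenario_spec")
}

scenario_duration <- function(spec) {
  sum(vapply(spec$segments, function(s) s$duration, 0))
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %d segments, %.1f s total, fs = %g Hz, seed = %d\n",
              length(x$segments), scenario_duration(x), 1 / x$sample_interval,
              x$seed))
  for (s in x$segments) {
    cat(sprintf("  %-16s %6.1f s  rate %5s bpm  amplitude %5.1f mm\n", s$kind,
                s$duration, ifelse(is.na(s$rate), "-", format(s$rate)),
                s$amplitude))
  }
  invisible(x)
}

#' Generate a radar chest-distance trace with ground truth
#'
#' Breathing segments are raised-cosine cycles: within one cycle the distance
#' falls from the exhale-end baseline to `baseline - amplitude` at full
#' inhale and returns (inhale = distance decreases, exhale = distance
#' increases). Per-cycle periods are jittered with coefficient of variation
#' `period_jitter_cv` and rescaled so each breathing segment holds an exact
#' integer number of cycles, `round(duration * rate / 60)`. A segment
#' immediately followed by a breath-hold stops a quarter-cycle in (mid
#' inhale), so the hold is entered with non-zero slope and its onset is a
#' well-defined corner; the hold freezes that level and the following
#' breathing segment resumes from the same phase. Motion transients ramp the
#' baseline by the segment amplitude (alternating sign) over `motion_ramp`
#' seconds with elevated noise while the body settles.
#'
#' @param spec a [scenario_spec()].
#' @return list with `trace` (a [radar_trace()]) and `truth`, a
#'   `ground_truth` list carrying `cycle_boundaries` (exhale-end times, s),
#'   `segments` (a data.frame with per-segment start/end/kind/rate/amplitude),
#'   `motion_intervals` and `hold_intervals` (data.frames with start/end).
#' @export
generate_radar_trace <- function(spec) {
  if (!inherits(spec, "scenario_spec")) {
    stop_odr("invalid_spec", "spec must be a scenario_spec")
  }
  dt <- spec$sample_interval
  total <- scenario_duration(spec)
  n <- round(total / dt)
  tt <- (seq_len(n) - 1) * dt

  clean <- numeric(n)
  extra_sd <- numeric(n)
  baseline <- spec$baseline_distance
  phase_frac <- 0          # cycle phase in [0, 1) carried across segments
  level <- baseline        # current chest level (for holds)
  motion_sign <- 1
  t0 <- 0
  boundaries <- numeric(0)
  seg_rows <- list()
  motion_iv <- list()
  hold_iv <- list()

  with_seed(spec$seed, {
    for (si in seq_along(spec$segments)) {
      seg <- spec$segments[[si]]
      t1 <- t0 + seg$duration
      idx <- which(tt >= t0 - 1e-9 & tt < t1 - 1e-9)
      nxt <- if (si < length(spec$segments)) spec$segments[[si + 1]]$kind else ""

      if (seg$kind == "breathing") {
        # a hold is entered mid-inhale (quarter phase) so its onset is a
        # crisp corner; a slump interrupts breathing mid-cycle (half phase)
        # since people move on cue, not at a breath boundary
        end_frac <- switch(nxt, breath_hold = 0.25, motion_transient = 0.5, 0)
        res <- breathing_phase(seg, t0, phase_frac, end_frac,
                               spec$period_jitter_cv)
        u <- stats::approx(res$knot_t, res$knot_u, xout = tt[idx],
                           rule = 2)$y
        clean[idx] <- baseline - (seg$amplitude / 2) * (1 - cos(2 * pi * u))
        boundaries <- c(boundaries, res$boundaries)
        phase_frac <- end_frac
        level <- baseline - (seg$amplitude / 2) * (1 - cos(2 * pi * end_frac))
      } else if (seg$kind %in% c("breath_hold", "apnea")) {
        clean[idx] <- level
        hold_iv[[length(hold_iv) + 1L]] <- c(t0, t1)
      } else { # motion_transient
        step <- if (seg$amplitude > 0) seg$amplitude else 100
        step <- motion_sign * step
        motion_sign <- -motion_sign
        ramp <- min(spec$motion_ramp, seg$duration)
        tau <- pmin(pmax((tt[idx] - t0) / ramp, 0), 1)
        clean[idx] <- level + step * (1 - cos(pi * tau)) / 2
        extra_sd[idx] <- spec$motion_noise_sd
        baseline <- baseline + step
        level <- baseline
        phase_frac <- 0
        motion_iv[[length(motion_iv) + 1L]] <- c(t0, t1)
      }
      seg_rows[[si]] <- data.frame(start = t0, end = t1, kind = seg$kind,
                                   rate = seg$rate, amplitude = seg$amplitude,
                                   stringsAsFactors = FALSE)
      t0 <- t1
    }
    if (spec$noise_sd > 0 || any(extra_sd > 0)) {
      clean <- clean + stats::rnorm(n, 0, sqrt(spec$noise_sd^2 + extra_sd^2))
    }
  })
  clean <- clean + spec$drift_rate * tt

  truth <- structure(list(
    cycle_boundaries = boundaries,
    segments = do.call(rbind, seg_rows),
    motion_intervals = interval_df(motion_iv),
    hold_intervals = interval_df(hold_iv)
  ), class = "ground_truth")
  list(trace = radar_trace(clean, dt, 0), truth = truth)
}

interval_df <- function(lst) {
  if (!length(lst)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  m <- do.call(rbind, lst)
  data.frame(start = m[, 1], end = m[, 2])
}

# Phase timeline for one breathing segment: phase runs from start_frac to
# m + end_frac over exactly `duration` seconds, where m is chosen so the
# mean period is ~60/rate. Returns knot times/phases for interpolation and
# the absolute times of integer-phase crossings (exhale-end boundaries).
breathing_phase <- function(seg, t_start, start_frac, end_frac, jitter_cv) {
  target <- seg$duration * seg$rate / 60
  m <- max(1L, round(target + start_frac - end_frac))
  u0 <- start_frac
  u1 <- m + end_frac
  ints <- seq(ceiling(u0 + 1e-9), floor(u1 - 1e-9))
  knot_u <- unique(c(u0, ints, u1))
  cyc_idx <- floor(head(knot_u, -1) + 1e-9)          # cycle owning each span
  slots <- sort(unique(cyc_idx))
  w <- pmax(0.5, 1 + jitter_cv * stats::rnorm(length(slots)))
  names(w) <- as.character(slots)
  span_dur <- diff(knot_u) * w[as.character(cyc_idx)] * (60 / seg$rate)
  span_dur <- span_dur * seg$duration / sum(span_dur)
  knot_t <- t_start + c(0, cumsum(span_dur))
  is_int <- abs(knot_u - round(knot_u)) < 1e-9
  list(knot_t = knot_t, knot_u = knot_u, boundaries = knot_t[is_int])
}

#' Complete ground-truth breath cycles
#'
#' Pairs of consecutive programmed cycle boundaries that fall inside a
#' single breathing segment (partial cycles cut off by a hold or slump are
#' not complete cycles and are excluded).
#'
#' @param truth a `ground_truth`.
#' @return data.frame with `start`, `end`, `period` (s) and `rate` (bpm).
#' @export
truth_cycles <- function(truth) {
  seg <- truth$segments
  out <- list()
  for (i in which(seg$kind == "breathing")) {
    b <- truth$cycle_boundaries
    b <- b[b >= seg$start[i] - 1e-9 & b <= seg$end[i] + 1e-9]
    if (length(b) >= 2) {
      out[[length(out) + 1L]] <- data.frame(
        start = head(b, -1), end = b[-1], period = diff(b),
        rate = seg$rate[i])
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      period = numeric(0), rate = numeric(0)))
  }
  do.call(rbind, out)
}

#' Instantaneous programmed rate from ground truth
#'
#' @param truth a `ground_truth` object.
#' @param t times in seconds.
#' @return programmed respiration rate in bpm at each time (NA outside
#'   breathing segments).
#' @export
truth_rate_at <- function(truth, t) {
  seg <- truth$segments
  out <- rep(NA_real_, length(t))
  for (i in seq_len(nrow(seg))) {
    sel <- t >= seg$start[i] & t < seg$end[i]
    out[sel] <- if (seg$kind[i] == "breathing") seg$rate[i] else NA_real_
  }
  out
}

#' Derive a coupled respiration-belt reference trace
#'
#' The belt gauges chest-wall expansion force, so its signal is (up to gain,
#' lag and its own sensor noise) the negation of the radar chest-distance
#' excursion: belt force peaks when the chest is fully expanded, i.e. at a
#' radar distance minimum. The lag models acquisition-clock offset between
#' the two recording systems; it shifts the belt's timebase, which the
#' breath-hold alignment in the validation module is designed to recover.
#'
#' @param radar a [radar_trace()].
#' @param truth ground truth from [generate_radar_trace()] (reserved for
#'   baseline handling; the coupling itself is deterministic).
#' @param gain force units per mm (> 0).
#' @param lag belt clock offset in seconds (belt time = radar time + lag).
#' @param noise_sd belt sensor noise in force units.
#' @param seed integer seed for the belt noise.
#' @return a [belt_trace()].
#' @export
derive_belt_trace <- function(radar, truth = NULL, gain = 1, lag = 0,
                              noise_sd = 0.02, seed = 1L) {
  check_nonempty(radar, "radar")
  if (!is.finite(gain) || gain <= 0) stop_odr("invalid_spec", "gain must be > 0")
  force_sig <- gain * (max(radar$samples) - radar$samples)
  if (noise_sd > 0) {
    force_sig <- with_seed(seed,
      force_sig + stats::rnorm(length(force_sig), 0, noise_sd))
  }
  belt_trace(force_sig, radar$sample_interval, radar$start_time + lag)
}
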