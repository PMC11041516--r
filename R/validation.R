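#' Locate the synchronization breath-hold in a trace
#'
#' The validation protocol starts with ~5 s of comfortable breathing and a
#' 3 s breath-hold; the hold is the event the two recording systems are
#' synchronized on. Detection: low-pass the signal, find the first window of
#' length `min_hold` whose peak-to-peak excursion stays below
#' `quiet_threshold`, then refine the onset backwards to the (sub-sample,
#' linearly interpolated) time the signal last left the hold-level band.
#' Works identically on radar (mm) and belt (force) traces since the
#' threshold defaults to a fraction of the trace's overall excursion.
#'
#' @param trace a [radar_trace()] or [belt_trace()].
#' @param min_hold minimum quiet duration in seconds (default 2.5, catching
#'   the protocol's 3 s hold with margin).
#' @param quiet_threshold excursion bound defining "quiet", in the trace's
#'   units; default `NULL` = 10% of the central excursion (2.5th-97.5th
#'   percentile range) of the smoothed trace.
#' @param smoothing_cutoff low-pass cutoff (Hz) used by the detector.
#' @return list with `onset`, `end` (s) and `level` (trace units).
#' @export
detect_breath_hold <- function(trace, min_hold = 2.5, quiet_threshold = NULL,
                               smoothing_cutoff = 0.6) {
  check_nonempty(trace)
  dt <- trace$sample_interval
  x <- fir_lowpass(trace$samples, dt, smoothing_cutoff)
  tt <- trace_times(trace)
  if (is.null(quiet_threshold)) {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    quiet_threshold <- 0.1 * (q[2] - q[1])
  }
  w <- max(2L, round(min_hold / dt))
  if (w > length(x)) stop_odr("no_hold_found", "trace shorter than min_hold")
  p2p <- rolling_p2p(x, w)
  i0 <- which(p2p < quiet_threshold)[1]
  if (is.na(i0)) {
    stop_odr("no_hold_found", "no quiet interval of %.2f s below %.3g found",
             min_hold, quiet_threshold)
  }
  level <- stats::median(x[i0:(i0 + w - 1L)])
  inside <- abs(x - level) < quiet_threshold
  # walk back from the window start to the last excursion out of the band
  j <- i0
  while (j > 1L && inside[j - 1L]) j <- j - 1L
  onset <- tt[j]
  if (j > 1L) {
    # sub-sample refinement: linear crossing of the band edge
    d0 <- abs(x[j - 1L] - level); d1 <- abs(x[j] - level)
    if (d0 > d1) {
      frac <- (d0 - quiet_threshold) / (d0 - d1)
      onset <- tt[j - 1L] + min(max(frac, 0), 1) * dt
    }
  }
  k <- i0 + w - 1L
  while (k < length(x) && inside[k + 1L]) k <- k + 1L
  list(onset = onset, end = tt[k], level = level)
}

#' Synchronize belt and radar recordings on the breath-hold
#'
#' The two systems start recording at different moments (setup and
#' calibration delays); the shared 3 s breath-hold gives a common landmark.
#' The offset is the difference of the detected hold onsets; subtracting it
#' from belt times co-registers the recordings.
#'
#' @param radar a [radar_trace()].
#' @param belt a [belt_trace()].
#' @param ... passed to [detect_breath_hold()].
#' @return list with `radar_hold_onset`, `belt_hold_onset` and `offset`
#'   (belt time minus radar time, s).
#' @export
align_traces <- function(radar, belt, ...) {
  hr <- detect_breath_hold(radar, ...)
  hb <- detect_breath_hold(belt, ...)
  list(radar_hold_onset = hr$onset, belt_hold_onset = hb$onset,
       offset = hb$onset - hr$onset)
}

#' Peak-to-peak respiration periods from one trace
#'
#' Detects breath peaks (radar: exhale-end distance maxima; belt: force
#' maxima — the belt is negated relative to the radar, so the same "maxima"
#' convention compares like with like after the signal is standardized) and
#' returns successive peak-to-peak periods. Peak detection reuses the
#' tracker's hysteresis segmentation with gates scaled to the trace's units.
#'
#' @param trace a trace of either modality.
#' @param cfg optional [tracker_config()] with gates in the trace's units;
#'   default `NULL` auto-scales the default config by the trace's central
#'   excursion so belt force units work unchanged.
#' @param invert detect minima instead of maxima (set `TRUE` to extract
#'   radar *inhale* peaks); belt traces derived by [derive_belt_trace()]
#'   need `invert = FALSE` since belt force maxima are its breath peaks.
#' @return data.frame with `peak_time` (time of the period's closing peak,
#'   s) and `period` (s).
#' @export
peak_periods <- function(trace, cfg = NULL, invert = FALSE) {
  check_nonempty(trace)
  if (is.null(cfg)) {
    q <- stats::quantile(trace$samples, c(0.025, 0.975), names = FALSE)
    span <- max(q[2] - q[1], .Machine$double.eps)
    cfg <- tracker_config(min_excursion = 0.15 * span,
                          max_excursion = 1e6 * span,
                          sample_interval = trace$sample_interval)
  }
  filt <- preprocess(trace, cfg)
  xx <- if (invert) -filt$samples else filt$samples
  core <- seg_core(trace_times(filt), xx, cfg)
  pk <- core$extrema$time[core$extrema$type == "max"]
  if (length(pk) < 2) {
    stop_odr("insufficient_peaks", "need >= 2 peaks, found %d", length(pk))
  }
  data.frame(peak_time = pk[-1], period = diff(pk))
}

#' Signed per-cycle period error between radar and belt
#'
#' Pairs radar and belt cycles greedily by nearest closing-peak time within
#' `max_pairing_gap` and reports the signed differences radar minus belt.
#' The sign is retained deliberately: a single shifted peak yields one
#' positive and one negative adjacent error that cancel, leaving the rate
#' over several cycles unaffected — the statistic of interest is therefore
#' the signed mean and its spread, not the absolute error.
#'
#' @param radar_periods,belt_periods data.frames from [peak_periods()], on a
#'   common clock (apply the [align_traces()] offset to belt peak times
#'   first).
#' @param max_pairing_gap maximum peak-time distance for a pair, s; default
#'   `NULL` = half the median radar period.
#' @return a `period_error_report`: list with `paired_errors`, `n_cycles`,
#'   `mean_error`, `sd_error` (sample SD, n-1), `unmatched_radar`,
#'   `unmatched_belt` and the per-pair table `pairs`.
#' @export
compare_periods <- function(radar_periods, belt_periods,
                            max_pairing_gap = NULL) {
  if (!nrow(radar_periods) || !nrow(belt_periods)) {
    stop_odr("empty_input", "both period sequences must be non-empty")
  }
  if (is.null(max_pairing_gap)) {
    max_pairing_gap <- stats::median(radar_periods$period) / 2
  }
  cand <- expand.grid(i = seq_len(nrow(radar_periods)),
                      j = seq_len(nrow(belt_periods)))
  cand$gap <- abs(radar_periods$peak_time[cand$i] -
                  belt_periods$peak_time[cand$j])
  cand <- cand[cand$gap <= max_pairing_gap, , drop = FALSE]
  cand <- cand[order(cand$gap), , drop = FALSE]
  used_i <- logical(nrow(radar_periods)); used_j <- logical(nrow(belt_periods))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      radar_time = radar_periods$peak_time[i],
      belt_time = belt_periods$peak_time[j],
      radar_period = radar_periods$period[i],
      belt_period = belt_periods$period[j],
      error = radar_periods$period[i] - belt_periods$period[j])
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(radar_time = numeric(0), belt_time = numeric(0),
               radar_period = numeric(0), belt_period = numeric(0),
               error = numeric(0))
  pairs <- pairs[order(pairs$radar_time), , drop = FALSE]
  errs <- pairs$error
  structure(list(
    paired_errors = errs,
    n_cycles = length(errs),
    mean_error = if (length(errs)) mean(errs) else NA_real_,
    sd_error = if (length(errs) > 1) stats::sd(errs) else NA_real_,
    unmatched_radar = sum(!used_i),
    unmatched_belt = sum(!used_j),
    pairs = pairs
  ), class = "period_error_report")
}

#' @export
print.period_error_report <- function(x, ...) {
  cat(sprintf(
    "<period_error_report> n = %d cycles, mean error %.4f s (SD %.4f s), unmatched radar/belt = %d/%d\n",
    x$n_cycles, x$mean_error, x$sd_error, x$unmatched_radar, x$unmatched_belt))
  invisible(x)
}

#' Belt-vs-radar validation, end to end
#'
#' Aligns the two traces on the breath-hold, extracts peak-to-peak periods
#' from each and compares them. Belt force peaks occur at full chest
#' expansion, which is a radar distance *minimum*, so the radar side uses
#' its inhale peaks (`invert = TRUE`) to give both period sequences
#' simultaneous landmarks; the period values themselves are unaffected by
#' which peak type closes them.
#'
#' @param radar,belt the two recordings.
#' @param ... passed to [compare_periods()].
#' @return the `period_error_report`, with the `sync` result attached.
#' @export
validate_pair <- function(radar, belt, ...) {
  sync <- align_traces(radar, belt)
  rp <- peak_periods(radar, invert = TRUE)
  bp <- peak_periods(belt)
  bp$peak_time <- bp$peak_time - sync$offset
  rep <- compare_periods(rp, bp, ...)
  rep$sync <- sync
  rep
}

#' Two-panel validation figure
#'
#' Top: the two standardized traces overlaid on the co-registered clock.
#' Bottom: per-cycle periods from both sources with the signed error.
#'
#' @param radar,belt the two recordings.
#' @param report a report from [validate_pair()] (computed if missing).
#' @export
plot_validation <- function(radar, belt, report = NULL) {
  if (is.null(report)) report <- validate_pair(radar, belt)
  off <- report$sync$offset
  std <- function(v) (v - mean(v)) / max(stats::sd(v), .Machine$double.eps)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(trace_times(radar), std(radar$samples), type = "l",
                 col = "blue", xlab = "time (s)", ylab = "standardized signal",
                 main = "radar (blue) vs belt (red)")
  graphics::lines(trace_times(belt) - off, std(belt$samples), col = "red")
  p <- report$pairs
  ylim <- range(c(p$radar_period, p$belt_period, p$error), na.rm = TRUE)
  graphics::plot(p$radar_time, p$radar_period, type = "b", col = "blue",
                 ylim = ylim, xlab = "time (s)", ylab = "period (s)",
                 main = sprintf("periods; mean error %.3f (SD %.3f) s",
                                report$mean_error, report$sd_error))
  graphics::lines(p$radar_time, p$belt_period, type = "b", col = "red")
  graphics::lines(p$radar_time, p$error, type = "h", col = "black")
  graphics::abline(h = 0, lty = 3)
  invisible(report)
}
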