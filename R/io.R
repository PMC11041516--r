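#' Read and write trace CSV files
#'
#' The interchange format is a two-column CSV with header `time_s,value`,
#' one row per sample, times strictly increasing and uniformly spaced.
#'
#' @param path file path.
#' @param kind `"radar"` or `"belt"`, selecting the class of the returned
#'   trace.
#' @return [read_trace()] returns a trace; [write_trace()] returns the path,
#'   invisibly.
#' @export
read_trace <- function(path, kind = c("radar", "belt")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_odr("format", "no such file: %s", path)
  df <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                 error = function(e) stop_odr("format", "unreadable CSV %s: %s",
                                              path, conditionMessage(e)))
  if (!identical(names(df), c("time_s", "value"))) {
    stop_odr("format", "expected header 'time_s,value' in %s", path)
  }
  if (!nrow(df)) stop_odr("format", "%s contains no samples", path)
  if (nrow(df) > 1) {
    dtv <- diff(df$time_s)
    if (any(dtv <= 0)) {
      stop_odr("format", "times not strictly increasing at row %d of %s",
               which(dtv <= 0)[1] + 1L, path)
    }
    if (max(dtv) - min(dtv) > 1e-6 * stats::median(dtv) + 1e-9) {
      stop_odr("format", "non-uniform sampling at row %d of %s",
               which.max(abs(dtv - stats::median(dtv))) + 1L, path)
    }
    dt <- stats::median(dtv)
  } else {
    dt <- 0.05
  }
  ctor <- if (kind == "radar") radar_trace else belt_trace
  ctor(df$value, dt, df$time_s[1])
}

#' @rdname read_trace
#' @param trace a trace to write.
#' @export
write_trace <- function(trace, path) {
  check_nonempty(trace)
  df <- data.frame(time_s = format(trace_times(trace), digits = 12,
                                   trim = TRUE, scientific = FALSE),
                   value = format(trace$samples, digits = 12, trim = TRUE,
                                  scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scenario specs as JSON
#'
#' The JSON schema mirrors [scenario_spec()]: top-level scalar fields plus a
#' `segments` array of `{duration, kind, rate, amplitude}` objects.
#'
#' @param spec a [scenario_spec()].
#' @param path JSON file path.
#' @export
write_scenario <- function(spec, path) {
  obj <- list(
    segments = lapply(spec$segments, function(s)
      list(duration = s$duration, kind = s$kind, rate = s$rate,
           amplitude = s$amplitude)),
    baseline_distance = spec$baseline_distance, noise_sd = spec$noise_sd,
    drift_rate = spec$drift_rate, seed = spec$seed,
    sample_interval = spec$sample_interval,
    period_jitter_cv = spec$period_jitter_cv,
    motion_ramp = spec$motion_ramp, motion_noise_sd = spec$motion_noise_sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- lapply(obj$segments, function(s) {
    rate <- s$rate
    if (is.null(rate) || !length(rate) || !is.numeric(rate)) rate <- NA_real_
    breathing_segment(s$duration, s$kind, rate = rate,
                      amplitude = if (is.null(s$amplitude)) 0 else s$amplitude)
  })
  scenario_spec(segs,
                baseline_distance = obj$baseline_distance %||% 1000,
                noise_sd = obj$noise_sd %||% 0.25,
                drift_rate = obj$drift_rate %||% 0,
                seed = obj$seed %||% 1L,
                sample_interval = obj$sample_interval %||% 0.05,
                period_jitter_cv = obj$period_jitter_cv %||% 0.05,
                motion_ramp = obj$motion_ramp %||% 1.5,
                motion_noise_sd = obj$motion_noise_sd %||% 5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground truth as JSON
#' @param truth a `ground_truth`.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(
    cycle_boundaries = truth$cycle_boundaries,
    segments = truth$segments,
    motion_intervals = truth$motion_intervals,
    hold_intervals = truth$hold_intervals
  ), path, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Alert log as JSON lines
#' @param log an `alert_log`.
#' @param path output path (one JSON object per event).
#' @export
write_alert_log <- function(log, path) {
  con <- file(path, "w"); on.exit(close(con))
  ev <- log$events
  for (i in seq_len(nrow(ev))) {
    writeLines(jsonlite::toJSON(list(
      time_s = ev$time[i], kind = ev$kind[i],
      triggering_rate_bpm = ev$triggering_rate[i],
      condition_duration_s = ev$condition_duration[i]
    ), auto_unbox = TRUE, digits = NA, null = "null", na = "null"), con)
  }
  invisible(path)
}
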