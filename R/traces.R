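#' Uniformly sampled chest-signal traces
#'
#' A trace is the package's basic time-series container: a start time, a
#' fixed sample interval and a numeric vector of samples. Radar traces carry
#' chest distance in millimetres (larger value = chest farther from the
#' sensor, so distance increases on exhale); belt traces carry chest-wall
#' force in arbitrary force units (force is maximal at full chest expansion,
#' i.e. at a radar distance minimum).
#'
#' @param samples numeric vector of samples; must be finite.
#' @param sample_interval sampling interval in seconds (> 0).
#' @param start_time time of the first sample in seconds.
#' @return An object of class `radar_trace` (resp. `belt_trace`), both
#'   inheriting from `odr_trace`.
#' @examples
#' tr <- radar_trace(1000 + sin(seq(0, 2 * pi, length.out = 50)),
#'                   sample_interval = 0.05)
#' trace_times(tr)[1:3]
#' @export
radar_trace <- function(samples, sample_interval = 0.05, start_time = 0) {
  new_trace(samples, sample_interval, start_time, "radar_trace", "mm")
}

#' @rdname radar_trace
#' @export
belt_trace <- function(samples, sample_interval = 0.05, start_time = 0) {
  new_trace(samples, sample_interval, start_time, "belt_trace", "force")
}

new_trace <- function(samples, sample_interval, start_time, class, unit) {
  samples <- as.numeric(samples)
  if (!is.numeric(sample_interval) || length(sample_interval) != 1 ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop_odr("invalid_spec", "sample_interval must be a single positive number")
  }
  if (length(samples) && any(!is.finite(samples))) {
    stop_odr("invalid_spec", "trace samples must all be finite")
  }
  structure(
    list(start_time = as.numeric(start_time)[1],
         sample_interval = sample_interval,
         samples = samples,
         unit = unit),
    class = c(class, "odr_trace")
  )
}

#' @rdname radar_trace
#' @param trace an `odr_trace`.
#' @export
trace_times <- function(trace) {
  if (!length(trace$samples)) return(numeric(0))
  trace$start_time + (seq_along(trace$samples) - 1) * trace$sample_interval
}

#' @export
length.odr_trace <- function(x) length(x$samples)

trace_duration <- function(trace) length(trace$samples) * trace$sample_interval

#' @export
print.odr_trace <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %.4g Hz, t = [%.2f, %.2f] s, unit = %s\n",
              class(x)[1], length(x$samples), 1 / x$sample_interval,
              x$start_time, x$start_time + trace_duration(x), x$unit))
  invisible(x)
}

#' @export
as.data.frame.odr_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), value = x$samples)
}

check_nonempty <- function(trace, what = "trace") {
  if (!inherits(trace, "odr_trace")) {
    stop_odr("invalid_spec", sprintf("%s must be an odr_trace", what))
  }
  if (!length(trace$samples)) {
    stop_odr("empty_input", sprintf("%s contains no samples", what))
  }
  invisible(trace)
}

# Single condition helper so callers can test on error classes
# (odr_<kind>_error) rather than matching messages.
stop_odr <- function(kind, msg, ...) {
  stop(structure(
    class = c(sprintf("odr_%s_error", kind), "odr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}
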