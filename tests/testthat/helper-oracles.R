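# Closed-form raised-cosine breathing waveform: the independent oracle for
# the tracker. Distance falls from `base` to `base - A` at full inhale and
# returns, period T; analytic extrema are at integer (maxima) and
# half-integer (minima) multiples of T.
analytic_breathing <- function(T, dur, A = 5, dt = 0.05, base = 1000) {
  tt <- seq(0, dur - dt / 2, by = dt)
  radar_trace(base - (A / 2) * (1 - cos(2 * pi * tt / T)), dt)
}

analytic_maxima <- function(T, dur) seq(0, dur, by = T)
analytic_minima <- function(T, dur) {
  m <- seq(T / 2, dur, by = T)
  m[m <= dur]
}

# Fraction of complete ground-truth cycles matched by an emitted cycle with
# both boundaries within `tol` seconds.
gt_match <- function(sim, tracked, tol = 0.5) {
  gt <- truth_cycles(sim$truth)
  hit <- vapply(seq_len(nrow(gt)), function(i) {
    any(abs(tracked$cycles$start_time - gt$start[i]) < tol &
        abs(tracked$cycles$end_time - gt$end[i]) < tol)
  }, TRUE)
  c(n = nrow(gt), matched = sum(hit))
}

# Synthetic period tables for compare_periods unit tests.
period_table <- function(periods, t0 = 10) {
  data.frame(peak_time = t0 + cumsum(periods), period = periods)
}

# Long coupled breathing scenario with a sync breath-hold, >= 50 cycles.
coupled_scenario <- function(seed = 1, breathe = 250) {
  scenario_spec(list(
    breathing_segment(5, rate = 12, amplitude = 5),
    breathing_segment(3, "breath_hold"),
    breathing_segment(breathe, rate = 14, amplitude = 5)
  ), seed = seed)
}
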