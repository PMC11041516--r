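test_that("preprocess preserves flat and band-limited signals", {
  flat <- radar_trace(rep(1000, 400), 0.05)
  expect_equal(preprocess(flat)$samples, flat$samples, tolerance = 1e-9)

  # noisy 15 bpm sinusoid correlates >= 0.99 with the clean waveform
  tt <- seq(0, 60 - 0.025, by = 0.05)
  clean <- 1000 - 2.5 * (1 - cos(2 * pi * tt / 4))
  set.seed(21)
  noisy <- radar_trace(clean + rnorm(length(tt), 0, 0.5), 0.05)
  f1 <- preprocess(noisy)
  expect_gt(cor(f1$samples, clean), 0.99)

  # near-idempotent on band-limited input: second pass changes < 1% RMS
  f1c <- preprocess(radar_trace(clean, 0.05))
  f2c <- preprocess(f1c)
  expect_lt(sqrt(mean((f2c$samples - f1c$samples)^2)) / sd(f1c$samples), 0.01)
})

test_that("segment_breaths matches analytic extrema on noiseless waveforms", {
  tr <- analytic_breathing(4, 20.5)
  res <- segment_breaths(preprocess(tr), tracker_config())
  expect_equal(nrow(res$cycles), 5)
  expect_lt(max(abs(res$cycles$period - 4)), 0.051)
  expect_lt(max(abs(res$cycles$start_time - seq(0, 16, by = 4))), 0.051)
  expect_lt(max(abs(res$cycles$inhale_peak_time - seq(2, 18, by = 4))), 0.051)
  expect_lt(max(abs(res$cycles$excursion - 5)), 0.1)
})

test_that("flat trace yields no cycles or motion; empty/mismatched input errors", {
  res <- segment_breaths(radar_trace(rep(1000, 1200), 0.05))
  expect_equal(nrow(res$cycles), 0)
  expect_equal(nrow(res$motion_events), 0)
  expect_false(any(res$rate_series$valid))
  expect_error(segment_breaths(radar_trace(numeric(0))),
               class = "odr_empty_input_error")
  expect_error(segment_breaths(radar_trace(1:10, sample_interval = 0.1)),
               class = "odr_config_error")
})

test_that("amplitude gating: sub-threshold excursions produce no cycles", {
  res <- segment_breaths(preprocess(analytic_breathing(4, 20.5, A = 0.3)))
  expect_equal(nrow(res$cycles), 0)
  # property: scaling any valid signal below the gate kills all cycles
  for (A in c(0.5, 0.7)) {
    r <- segment_breaths(preprocess(analytic_breathing(5, 30, A = A)))
    expect_equal(nrow(r$cycles), 0)
  }
})

test_that("a baseline step opens one motion event and no cycle overlaps it", {
  spec <- scenario_spec(list(
    breathing_segment(30, rate = 15, amplitude = 5),
    breathing_segment(2.5, "motion_transient", amplitude = 100),
    breathing_segment(30, rate = 15, amplitude = 5)
  ), seed = 5)
  sim <- generate_radar_trace(spec)
  res <- track(sim$trace)
  mi <- sim$truth$motion_intervals
  overlaps <- res$motion_events$start_time < mi$end[1] &
    res$motion_events$end_time > mi$start[1]
  expect_equal(sum(overlaps), 1)
  expect_equal(nrow(res$motion_events), 1)
  # structural invariant: no cycle intersects any motion event interior
  for (i in seq_len(nrow(res$motion_events))) {
    expect_false(any(res$cycles$start_time < res$motion_events$end_time[i] - 1e-9 &
                     res$cycles$end_time > res$motion_events$start_time[i] + 1e-9))
  }
  # the motion magnitude exceeds the gate
  expect_true(all(res$motion_events$magnitude > 20))
})

test_that("estimate_rate follows the most recent completed cycle", {
  cyc <- data.frame(start_time = c(0, 4), end_time = c(4, 11.5),
                    inhale_peak_time = c(2, 8), period = c(4, 7.5),
                    excursion = c(5, 5))
  e <- estimate_rate(cyc, 5)
  expect_true(e$valid)
  expect_equal(e$rate, 15)
  e2 <- estimate_rate(cyc, 12)
  expect_equal(e2$rate, 8)          # 60 / 7.5: the alert-threshold boundary
  expect_equal(e2$source_cycle, 2L)
  # staleness: estimates go invalid 15 s after the last cycle
  expect_true(estimate_rate(cyc, 26)$valid)
  expect_false(estimate_rate(cyc, 27)$valid)
  expect_false(estimate_rate(cyc, 3)$valid)     # no completed cycle yet
  expect_false(estimate_rate(cyc[0, ], 10)$valid)
  expect_false(estimate_rate(NULL, 10)$valid)
})

test_that("rate series recovers the programmed constant rate", {
  # deterministic limit: every valid estimate within 0.5 bpm of 15
  spec <- preset_scenario("position_tuning", noise_sd = 0,
                          period_jitter_cv = 0)
  res <- track(generate_radar_trace(spec)$trace)
  v <- res$rate_series$rate[res$rate_series$valid]
  expect_gt(length(v), 50)
  expect_true(all(v >= 14.5 & v <= 15.5))

  # default noise and jitter: medians across rates stay within 0.5 bpm
  for (r in c(6, 15, 20)) {
    spec <- scenario_spec(list(breathing_segment(60, rate = r, amplitude = 5)),
                          seed = 11)
    res <- track(generate_radar_trace(spec)$trace)
    v <- res$rate_series$rate[res$rate_series$valid]
    expect_lt(abs(median(v) - r), 0.5)
  }
})

test_that("cessation preset stops producing cycles after apnea onset", {
  sim <- generate_radar_trace(preset_scenario("cessation", seed = 6))
  res <- track(sim$trace)
  apnea_start <- sim$truth$segments$start[sim$truth$segments$kind == "apnea"]
  expect_false(any(res$cycles$start_time > apnea_start + 0.5))
  late <- res$rate_series$time > apnea_start + 16
  expect_false(any(res$rate_series$valid[late]))
})

test_that("overdose_simulation ground-truth cycles are recovered", {
  tot <- c(n = 0, matched = 0)
  for (s in 1:6) {
    sim <- generate_radar_trace(preset_scenario("overdose_simulation", seed = s))
    tot <- tot + gt_match(sim, track(sim$trace))
  }
  expect_gte(tot[["matched"]] / tot[["n"]], 0.9)
})

test_that("tracking result invariants hold across seeded scenarios", {
  for (s in c(2, 9)) {
    sim <- generate_radar_trace(preset_scenario("overdose_simulation", seed = s))
    res <- track(sim$trace)
    cyc <- res$cycles
    # time-ordered, non-overlapping, gated excursions, period consistency
    expect_true(all(diff(cyc$start_time) > 0))
    expect_true(all(cyc$end_time > cyc$start_time))
    expect_true(all(head(cyc$end_time, -1) <= cyc$start_time[-1] + 1e-9))
    expect_true(all(cyc$excursion >= 0.75 & cyc$excursion <= 20))
    expect_equal(cyc$period, cyc$end_time - cyc$start_time)
    expect_true(all(cyc$inhale_peak_time > cyc$start_time &
                    cyc$inhale_peak_time < cyc$end_time))
    me <- res$motion_events
    expect_true(all(me$end_time >= me$start_time))
    expect_true(all(me$magnitude > 20))
  }
})
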