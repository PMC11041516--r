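test_that("zero-amplitude and flat degenerate scenarios produce constant traces", {
  spec <- scenario_spec(list(breathing_segment(60, rate = 15, amplitude = 0)),
                        noise_sd = 0)
  sim <- generate_radar_trace(spec)
  expect_equal(length(sim$trace), 1200)
  expect_true(all(sim$trace$samples == spec$baseline_distance))
  expect_equal(nrow(sim$truth$motion_intervals), 0)
})

test_that("noiseless 15 bpm / 5 mm / 60 s trace has exactly 15 inhale minima", {
  spec <- scenario_spec(list(breathing_segment(60, rate = 15, amplitude = 5)),
                        noise_sd = 0, period_jitter_cv = 0)
  sim <- generate_radar_trace(spec)
  x <- sim$trace$samples
  mins <- which(diff(sign(diff(x))) > 0) + 1
  tt <- trace_times(sim$trace)
  expect_equal(sum(tt[mins] > 0 & tt[mins] <= 60), 15)
  # oracle: analytic minima of the programmed waveform
  expect_equal(tt[mins], analytic_minima(4, 60)[seq_along(mins)],
               tolerance = 0.051)
  # amplitude fidelity
  expect_equal(max(x) - min(x), 5, tolerance = 0.01)
})

test_that("generation is deterministic in the seed", {
  spec <- preset_scenario("overdose_simulation", seed = 7)
  a <- generate_radar_trace(spec)
  b <- generate_radar_trace(spec)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth$cycle_boundaries, b$truth$cycle_boundaries)
  c <- generate_radar_trace(preset_scenario("overdose_simulation", seed = 8))
  expect_false(identical(a$trace$samples, c$trace$samples))
})

test_that("cycle-count fidelity: duration D at rate r gives floor or ceil cycles", {
  for (case in list(c(45, 13), c(60, 6), c(31, 17), c(50, 9))) {
    spec <- scenario_spec(list(breathing_segment(case[1], rate = case[2],
                                                 amplitude = 5)),
                          noise_sd = 0, seed = 3)
    sim <- generate_radar_trace(spec)
    ncyc <- nrow(truth_cycles(sim$truth))
    expect_true(ncyc %in% c(floor(case[1] * case[2] / 60),
                            ceiling(case[1] * case[2] / 60)),
                label = sprintf("D=%g r=%g gave %d cycles", case[1], case[2], ncyc))
  }
})

test_that("invalid specs are rejected", {
  expect_error(breathing_segment(-1), class = "odr_invalid_spec_error")
  expect_error(breathing_segment(10, rate = 0), class = "odr_invalid_spec_error")
  expect_error(scenario_spec(list()), class = "odr_invalid_spec_error")
  expect_error(scenario_spec(list(breathing_segment(10, rate = 12, amplitude = 5)),
                             noise_sd = -1), class = "odr_invalid_spec_error")
  expect_error(preset_scenario("nope"), class = "odr_unknown_preset_error")
})

test_that("motion transients shift the baseline beyond the 20 mm gate", {
  spec <- preset_scenario("overdose_simulation", seed = 2, noise_sd = 0)
  sim <- generate_radar_trace(spec)
  tt <- trace_times(sim$trace)
  mi <- sim$truth$motion_intervals
  expect_equal(nrow(mi), 4)
  for (i in seq_len(nrow(mi))) {
    pre <- sim$trace$samples[tt < mi$start[i] & tt > mi$start[i] - 1][1]
    post <- sim$trace$samples[tt > mi$end[i] & tt < mi$end[i] + 0.3][1]
    expect_gt(abs(post - pre), 20)
  }
})

test_that("belt trace is phase-locked to the radar and respects lag", {
  spec <- scenario_spec(list(breathing_segment(60, rate = 15, amplitude = 5)),
                        noise_sd = 0, period_jitter_cv = 0)
  sim <- generate_radar_trace(spec)
  belt <- derive_belt_trace(sim$trace, sim$truth, gain = 1, lag = 0, noise_sd = 0)
  # phase identity: belt maxima coincide with radar minima
  bp <- peak_periods(belt)
  rmin <- peak_periods(sim$trace, invert = TRUE)
  expect_equal(bp$peak_time, rmin$peak_time, tolerance = 0.051)
  # lag shifts every peak time
  belt2 <- derive_belt_trace(sim$trace, sim$truth, lag = 0.2, noise_sd = 0)
  expect_equal(peak_periods(belt2)$peak_time, bp$peak_time + 0.2,
               tolerance = 0.051)
  # determinism and error paths
  b1 <- derive_belt_trace(sim$trace, seed = 5)
  b2 <- derive_belt_trace(sim$trace, seed = 5)
  expect_identical(b1$samples, b2$samples)
  expect_error(derive_belt_trace(radar_trace(numeric(0))),
               class = "odr_empty_input_error")
  expect_error(derive_belt_trace(sim$trace, gain = 0),
               class = "odr_invalid_spec_error")
})

test_that("coupling: lag-0 belt preserves the per-cycle period sequence", {
  sim <- generate_radar_trace(coupled_scenario(seed = 4, breathe = 100))
  belt <- derive_belt_trace(sim$trace, sim$truth, lag = 0, noise_sd = 0)
  rp <- peak_periods(sim$trace, invert = TRUE)
  bp <- peak_periods(belt)
  expect_equal(nrow(rp), nrow(bp))
  expect_equal(rp$period, bp$period, tolerance = 0.051)
})

test_that("presets encode the documented protocols", {
  ov <- preset_scenario("overdose_simulation")
  kinds <- vapply(ov$segments, function(s) s$kind, "")
  expect_identical(kinds, c("breathing", "motion_transient", "breathing",
                            "motion_transient", "breathing", "motion_transient",
                            "breathing", "motion_transient", "breathing"))
  expect_true(all(vapply(ov$segments[kinds == "breathing"],
                         function(s) s$duration, 0) == 30))

  rv <- preset_scenario("respiration_validation")
  holds <- Filter(function(s) s$kind == "breath_hold", rv$segments)
  expect_length(holds, 1)
  expect_equal(holds[[1]]$duration, 3)
  expect_equal(rv$segments[[1]]$duration, 5)

  pt <- preset_scenario("position_tuning")
  expect_true(all(vapply(Filter(function(s) s$kind == "breathing", pt$segments),
                         function(s) s$rate, 0) == 15))

  oi <- preset_scenario("oird_decline")
  rates <- vapply(oi$segments, function(s) s$rate, 0)
  expect_true(any(stats::na.omit(rates) < 8))
  expect_true(any(vapply(oi$segments, function(s) s$kind, "") == "apnea"))

  ce <- preset_scenario("cessation")
  apn <- Filter(function(s) s$kind == "apnea", ce$segments)
  expect_true(sum(vapply(apn, function(s) s$duration, 0)) >= 10)
})
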