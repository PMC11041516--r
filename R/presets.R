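#' Built-in test scenarios
#'
#' Scenario presets encode the bench protocols used to exercise the monitor:
#'
#' * `respiration_validation` — breathe comfortably for ~5 s, hold the
#'   breath for 3 s (the synchronization event the validation module aligns
#'   on), then keep breathing. Comfortable pace is modelled at 12 bpm with a
#'   5 mm excursion.
#' * `position_tuning` — rate held constant at 15 bpm for 60 s, the cue-paced
#'   protocol used when searching for the mounting position.
#' * `overdose_simulation` — five 30 s comfortable-breathing blocks (upright,
#'   then slumped forward / backward / left / right) separated by four large
#'   slump transients (100 mm baseline steps with 1-2 s of settling noise).
#'   Slumped blocks breathe shallower (3 mm) than upright (6 mm).
#' * `oird_decline` — opioid-induced respiratory depression: rate ramps
#'   15 -> 12 -> 10 bpm, drops below the 8 bpm alert threshold (6 bpm from
#'   t = 70 s), then stops entirely (apnea from t = 100 s).
#' * `cessation` — healthy breathing for 30 s, then >= 10 s of apnea.
#'
#' @param name preset identifier (see above).
#' @param seed integer seed stored in the returned spec.
#' @param ... overrides passed on to [scenario_spec()] (e.g. `noise_sd`).
#' @return a [scenario_spec()].
#' @export
preset_scenario <- function(name, seed = 1L, ...) {
  br <- function(d, r, a) breathing_segment(d, "breathing", rate = r, amplitude = a)
  segs <- switch(name,
    respiration_validation = list(
      br(5, 12, 5),
      breathing_segment(3, "breath_hold"),
      br(30, 12, 5)
    ),
    position_tuning = list(br(60, 15, 5)),
    overdose_simulation = {
      mt <- function() breathing_segment(2.5, "motion_transient", amplitude = 100)
      list(br(30, 14, 6), mt(), br(30, 14, 3), mt(), br(30, 14, 3), mt(),
           br(30, 14, 3), mt(), br(30, 14, 3))
    },
    oird_decline = list(
      br(30, 15, 5), br(20, 12, 5), br(20, 10, 5), br(30, 6, 4),
      breathing_segment(30, "apnea")
    ),
    cessation = list(br(30, 15, 5), breathing_segment(30, "apnea")),
    stop_odr("unknown_preset", "unknown preset '%s'", name)
  )
  scenario_spec(segs, seed = seed, ...)
}

#' @rdname preset_scenario
#' @export
preset_names <- function() {
  c("respiration_validation", "position_tuning", "overdose_simulation",
    "oird_decline", "cessation")
}

#' Time at which the oird_decline preset falls below the alert threshold
#'
#' Start of the first programmed breathing segment whose rate is below
#' `threshold`, and the onset of the subsequent apnea, computed from the
#' spec (used to bound expected alert times in tests).
#' @param spec a scenario spec.
#' @param threshold rate threshold in bpm.
#' @return list with `sub_threshold_onset`, `apnea_onset` and
#'   `max_cycle_period` (s) of the sub-threshold breathing.
#' @export
scenario_decline_times <- function(spec, threshold = 8) {
  t0 <- 0
  sub <- NA_real_; apn <- NA_real_; maxp <- 0
  for (seg in spec$segments) {
    if (seg$kind == "breathing" && is.finite(seg$rate) && seg$rate < threshold &&
        is.na(sub)) {
      sub <- t0
    }
    if (seg$kind == "breathing" && is.finite(seg$rate) && seg$rate < threshold) {
      maxp <- max(maxp, 60 / seg$rate)
    }
    if (seg$kind == "apnea" && is.na(apn)) apn <- t0
    t0 <- t0 + seg$duration
  }
  list(sub_threshold_onset = sub, apnea_onset = apn, max_cycle_period = maxp)
}
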