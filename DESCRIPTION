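Package: odradar
Title: Contactless Opioid-Overdose Detection from Radar Chest-Displacement Signals
Version: 0.1.0
Authors@R: person("ODR", "Maintainers", email = "odradar@example.org", role = c("aut", "cre"))
Description: Tools for developing and testing a radar-based opioid-overdose
    monitor. Provides a synthetic generator for quasi-periodic chest-distance
    traces (breathing, breath-holds, apnea, slump motion artifacts) with
    coupled respiration-belt references, a breath-cycle tracker that segments
    chest-displacement signals with amplitude gating (0.75-20 mm) and motion
    rejection, an overdose alert state machine (sustained sub-8 bpm rate and
    10 s respiration cessation triggers), signed per-cycle period-error
    statistics for two-source validation with breath-hold synchronization,
    and field-of-view placement geometry for mounting the sensor in a
    restroom stall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
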