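---
title: "Methods: breath tracking, overdose alerting and validation in odradar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath tracking, overdose alerting and validation in odradar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odradar)
```

## The problem

Fatal opioid overdoses act through respiratory depression: breathing slows
below roughly 8 breaths per minute (bpm), then stops. A pulsed-coherent
radar mounted in a restroom stall observes the occupant's chest as a 1-D
relative distance signal with sub-millimetre resolution, with no camera and
no identifying data. `odradar` implements the computational chain of such a
monitor — breath segmentation, rate estimation, alert logic, two-source
validation statistics and mounting geometry — together with a synthetic
signal generator that stands in for recorded human data.

## Signal model and the simulator

A breathing cycle is modelled as a raised cosine in chest distance: from the
exhale-end baseline the distance falls to `baseline - A` at full inhale and
returns, where `A` is the peak-to-trough excursion in mm (inhale = chest
toward the sensor = distance decreases). Defaults: 20 Hz sampling (more than
60 samples per cycle over the 4-20 bpm design band), baseline 1000 mm (the
middle of the 0.75-1.5 m operating range), additive white Gaussian sensor
noise with SD 0.25 mm, and per-cycle period jitter with a 5% coefficient of
variation so that periods have realistic spread.

Three modelling choices deserve explanation:

* **Integer cycles per segment.** Jittered periods are rescaled so each
  breathing segment contains exactly `round(duration * rate / 60)` cycles.
  This keeps the programmed ground truth (cycle boundaries, apnea onsets)
  exact, at the cost of a per-segment rate error below half a cycle.
* **Breath-holds start mid-inhale.** A hold entered at a waveform extremum
  has zero slope at the junction, which makes its onset physically
  unresolvable at sub-second precision. People hold their breath after
  inhaling, so the generator ends the preceding segment a quarter-cycle in
  (level `baseline - A/2`), giving the hold a crisp corner. Breathing
  resumes from the same phase after the hold.
* **Slumps interrupt mid-cycle.** Motion transients (smooth baseline steps
  of 100 mm over 1.5 s, with 5 mm SD settling noise, alternating direction)
  begin half a cycle into the final breath, because people move on cue, not
  at breath boundaries. The interrupted half-breath is not a ground-truth
  cycle.

What the generator does *not* emulate: radio-frequency propagation, range
binning, multi-person scenes, clothing, posture-dependent reflectivity, or
genuinely pathological breathing waveshapes. A green test therefore
establishes that the algorithms are correct against the stated signal
model, not that the physical device meets clinical performance.

## Breath segmentation

The tracker low-passes the trace with a zero-phase windowed-sinc filter
(cutoff 1 Hz: passes breathing up to 60 bpm, suppresses sensor noise;
symmetric kernels displace no peaks). Edges use odd reflection pivoted on a
5-sample local mean, so extrema near the trace ends are neither flattened
nor perturbed by single noisy edge samples.

Direction changes are detected with hysteresis: a candidate extremum is
committed once the signal retraces at least `min_excursion` (0.75 mm, the
smallest trackable breath) from it. This operationalizes the lower amplitude
bound as noise immunity and guarantees every committed phase excursion is at
least 0.75 mm; the bound is applied per phase. A cycle runs exhale-end
(distance maximum) to the next exhale-end, with the interior minimum as the
inhale peak; the current rate is 60 divided by the most recent completed
cycle's period, going stale 15 s after the last cycle. Cycles faster than
`min_period` (1.5 s, twice the 20 bpm design maximum) are discarded as
residual noise.

Any phase excursion beyond `max_excursion` (20 mm) is body motion: a motion
event opens, the partial cycle is dropped, and tracking recalibrates. The
event closes at the re-stabilization point — the start of the first
2 s window (`motion_blank_time`) in which the signal stays inside a 20 mm
band — and that confirmation window is then *replayed* through a fresh
tracker state, so breaths resumed during confirmation are recovered without
ever emitting a cycle that overlaps the motion event. At the very end of a
trace a pending extremum is committed if the retrace reached half the
hysteresis bound; without this boundary policy the final cycle of a
recording is systematically lost.

## Alert logic

Thresholds follow the consulted-expert danger criteria: rate below 8 bpm
sustained for 15 s **or** 2 full breaths (read as a disjunction — the
sentence says "or" — and both paths are configurable), and a cessation
trigger after 10 s without respiratory motion. Design choices where the
source logic is underdetermined:

* Invalid rate estimates (tracking gaps without body motion) do not reset
  the 15 s window: a fading signal must not defeat both triggers. They feed
  the cessation path instead.
* A single fast breath resets the breath-count path but not a
  still-satisfied window condition.
* Body motion *suspends* the cessation clock rather than resetting it: a
  moving body is not a silent one, but motion is no evidence of breathing.
* Sub-cycle "respiratory motion" is a smoothed-derivative channel: the
  chest is moving with breathing wherever the derivative-of-Gaussian slope
  (sigma 0.3 s) of the filtered distance exceeds 0.5 mm/s — about five
  times the derivative noise floor at the default sensor noise, and well
  below the ~1.2-3.8 mm/s breathing slopes across the design band. Very
  shallow, very slow breathing (0.75 mm at 4 bpm peaks near 0.16 mm/s)
  falls below this channel and is covered by the cycle stream alone.
* Alerts latch until an explicit reset; re-arming policy is out of scope.

## Validation statistics

The reference modality is a respiration belt, modelled as the negated radar
excursion (force is maximal at full chest expansion, a radar distance
minimum) with its own gain, clock offset and noise. The shared 3 s
breath-hold synchronizes the two clocks: the hold is found as the first
2.5 s window whose low-passed excursion stays below 10% of the trace's
central excursion, with the onset refined to the sub-sample time the signal
last left the hold-level band. The offset (belt onset minus radar onset) is
recovered to well under one sample because both detectors share the same
systematic bias, which cancels in the difference.

Per-cycle periods are peak-to-peak differences. Because belt peaks coincide
with radar inhale peaks, the end-to-end comparison pairs belt force maxima
with radar distance minima (simultaneous landmarks); pairing is greedy
nearest-peak-time within half the median period. Errors are signed (radar
minus belt, our orientation choice): a single shifted peak yields one
positive and one negative adjacent error that cancel, so the mean signed
error — not the absolute error — is what bounds the rate bias over time. SD
uses the sample (n-1) denominator. On coupled synthetic traces at default
noise the suite requires |mean| <= 0.05 s and SD <= 0.2 s over >= 50 cycles;
this is an internal-consistency band for the stated signal model, not a
reproduction of any human-data agreement figure.

## Geometry

Frame: origin at seat centre on the seat plane, x toward the door, z up.
The default mounting (85 cm forward of the chest axis, 85 cm above the
seat, 30 degrees down, 45 degrees out from the wall) aims the boresight
~36 cm above the seat; the range to the chest target 35 cm above the seat
is sqrt(0.85^2 + 0.50^2) = 0.99 m, and the inverse tilt to that target is
atan(50/85) = 30.5 degrees. A point is covered when its horizontal and
vertical off-axis angles are within half of the 65 x 53 degree capture
cone and it lies ahead of the sensor. The five default posture targets
(upright plus four slump directions) are modelled, not measured; their
coordinates are exposed so other posture sets can be evaluated.

## Numerical and boundary choices

* Sampling-rate mismatch between a trace and the tracker configuration is a
  hard error, not a resample.
* The FIR transition width is 0.5 Hz with a Hamming window; double
  filtering changes a band-limited signal by ~0.2% RMS.
* Greedy pairing and hold detection are deterministic; all simulator
  randomness flows from the scenario seed, and identical specs are
  bit-reproducible.
* Degenerate inputs (empty traces, flat traces, missing holds, fewer than
  two peaks) raise classed conditions (`odr_*_error`) rather than returning
  partial results.

## Known limitations

The breath-before-a-slump whose closing reversal is swallowed by the step
is unrecoverable by any direction-change tracker; post-motion boundary
jitter under settling noise can displace the first recovered cycle by a few
hundred milliseconds. Rate estimation reports the last completed cycle, so
it lags genuine rate changes by up to one period. The activity channel's
slope threshold trades shallow-slow-breathing sensitivity against false
silence resets; its rationale is given above and it is configurable.
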