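---
title: "Quantifying bradykinesia and rigidity from wearable gyroscopes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bradykinesia and rigidity from wearable gyroscopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bradykin)
```

## The measurement problem

Bradykinesia — slowness of voluntary movement with a progressive reduction
in the speed and amplitude of repetitive actions — and cogwheel rigidity are
cardinal motor signs of Parkinson's disease. Clinical rating (UPDRS part
III) is ordinal and rater-dependent; body-worn magneto-inertial units offer
an objective alternative. This package implements a complete analysis chain
for three UPDRS tasks recorded with 3-axis gyroscopes at five upper-limb
sites (index finger, thumb, metacarpus, wrist, arm): finger tapping (item
23, 15 repetitions), hand prono-supination (item 25, 15 repetitions), and
passive elbow flexion-extension for rigidity (item 22, 10 repetitions).

Four kinematic indexes are extracted per recording:

* **Total time** `t_TOT = t_b - t_a`: the time between the start of the
  first movement cycle and the end of the last.
* **Fatigability** `m`: the slope of the ordinary-least-squares line
  `y = m x + q` fitted to the per-cycle peak-to-peak angular velocity `y`
  against the cycle number `x = 1..n`, on the task's most informative
  gyroscope axis (y for tapping, x for prono-supination). Negative slopes
  quantify decrement.
* **Total power**: the integral over frequency of the power spectral
  density of the band-passed angular velocity. By Parseval's theorem this
  equals the signal's mean-square content and proxies overall movement
  intensity.
* **Smoothness** (SPARC): the negative arc length of the normalised
  magnitude Fourier spectrum of the speed profile `v(t)`,

  `SAL = -∫₀^ωc sqrt[(1/ωc)² + (dV̂(ω)/dω)²] dω`, `V̂(ω) = V(ω)/V(0)`,

  with the cutoff `ωc` the smaller of an upper bound (4 Hz for the
  bradykinesia tasks, 20 Hz for the passive rigidity movement) and the
  highest frequency at which `V̂` still reaches the threshold `V̄ = 0.10`.
  Normalisation by `V(0)` makes the measure exactly amplitude-invariant;
  fragmented, hesitant movements have richer spectra and more negative
  values.

The cohort layer mirrors a three-group design — patients in the OFF state
(≥ 12 h medication withdrawal), the same patients ON medication, and
healthy subjects — with two-way repeated-measures ANOVA (state × sensor
location, both within-subject), mixed-design ANOVA (group between, location
within), per-location post hoc t-tests compared against the Bonferroni
threshold α/(number of comparisons) (0.05/5 = 0.01), paired/independent
t-tests for total time, and squared Pearson correlations against the UPDRS
item scores bundled with the package.

## Preprocessing

Gyroscope channels are filtered with zero-phase (forward–backward)
Butterworth filters, odd-reflection padded at the edges: a 4th-order 1 Hz
high-pass removes drift and gross orientation change, and 4th-order
band-passes isolate the bradykinesia (1–4 Hz) and tremor (4–8 Hz) bands.
Zero-phase filtering preserves cycle boundary timing; the forward–backward
pass doubles the effective attenuation (a 6 Hz tone is ~21 dB down in the
bradykinesia band, measured in the test suite).

Which signal feeds which stage is a deliberate design choice:

* **Segmentation and peak-to-peak amplitudes** use the 1 Hz high-passed
  (drift-removed) signal, *not* the 1–4 Hz band. Tap bursts are brief
  relative to the repetition period, so much of their energy sits in
  harmonics above 4 Hz; band-passing smears bursts into one another at 2–3
  Hz repetition rates and attenuates the peak-to-peak amplitudes by a
  cycle-shape-dependent factor that biases the fatigability slope by far
  more than the 1% recovery error the drift-removed signal achieves.
* **Total power** integrates the PSD of the 1–4 Hz band-passed signal:
  this is the index meant to isolate the movement band.
* **SPARC** consumes the drift-removed speed profile without further band
  filtering: the normalised-spectrum arc length is inherently low-pass and
  its own cutoff rule bounds the band.

The speed profile `v(t)` can be the absolute angular speed of the task axis
(`task_axis_abs`, the segmentation default — boundaries are sharpest on the
dominant axis) or the Euclidean norm of the three gyro channels
(`gyro_norm`, the smoothness default — fluidity is a property of the whole
rotation). Both are exposed; the choice is a config switch.

## Segmentation

Movement cycles are detected on the non-negative speed profile in two
passes. Pass 1 finds runs above 10% of the *global* peak, merges runs
separated by less than `min_gap = 0.15` s (a tap's opening and closing
phases pass through zero speed mid-cycle), and drops runs shorter than
`min_duration = 0.1` s. Pass 2 re-anchors each burst's boundaries at the
nearest crossings of 10% of *that burst's own* peak, realising a per-cycle
threshold; expansion is limited at the speed minimum between neighbouring
bursts so cycles never overlap. Crossings are taken at the first sample at
or above threshold (no sub-sample interpolation; ties resolve to the
earliest sample). The expected repetition count (15 or 10) is metadata
only: a mismatch logs a warning, because patients' actual performance
varies.

`min_gap` and `min_duration` are not prescribed by any task definition;
0.15 s and 0.1 s were chosen so that intra-cycle speed dips merge while
inter-cycle rests (≈ 0.59 of the base period in the generator's geometry)
separate, for repetition rates from 1 to 3 Hz.

## Numerical choices

* **PSD**: Welch's method, Hann window, 50% overlap, segments of
  `min(512, N)` samples — 4 s at the 128 Hz default rate, i.e. 0.25 Hz
  resolution. At 0.5 Hz resolution the Hann mainlobes of movement
  harmonics 1 Hz apart overlap, and with a 50% hop their cross-term is
  phase-locked rather than averaging out, biasing two-tone power by over
  10%; 0.25 Hz resolution restores additivity to better than 0.01%.
  Records shorter than one segment fall back to a single-segment
  periodogram. One-sided density scaling; the index integrates the PSD by
  the trapezoidal rule over 0 to Nyquist.
* **SPARC spectrum**: FFT zero-padded until the frequency grid is at least
  0.05 Hz fine; arc length by summation over the discrete grid on
  (0, ωc]. The adaptive cutoff scans for the last grid frequency with
  `V̂ ≥ V̄`; if no frequency beyond DC qualifies, the first grid interval
  is used and the case is logged. An all-zero profile (V(0) = 0) is an
  explicit undefined-result error.
* **Fatigability**: `stats::lm` on cycle number 1..n; at least two cycles
  required; the fit r² is reported alongside the slope.
* **ANOVA**: `stats::aov` with `Error()` strata — each within-subject
  effect is tested against its own subject-interaction mean square.
  Degrees of freedom are reported uncorrected (no sphericity correction by
  default, matching the integer-df reporting style of the clinical
  literature); subjects with incomplete cells are dropped listwise with a
  message. Independent t-tests default to pooled variance with a Welch
  option.

## The synthetic-movement generator

No patient recordings are distributed, so the package ships a generator
whose outputs have the statistical structure the analysis assumes. One
movement cycle is a symmetric open–close pair of Gaussian angular-velocity
pulses on the task axis (pulse σ = T₀/20 for base period T₀; open and
close centres 0.2 T₀ apart), normalised so cycle k peaks at exactly
`base_amplitude + (k-1) · decay_per_cycle` (floored at 5% of base, with a
metadata warning if the floor is hit early). The symmetric pair makes the
peak-to-peak exactly twice the peak, so the fatigability ground truth is
`2 × decay_per_cycle`. Arrhythmicity multiplies inter-cycle intervals by
lognormal-like jitter; 10% of the task-axis signal leaks onto the other
gyro axes (so most-relevant-axis selection is testable); tremor is an
additive 4–8 Hz sinusoid; sensor noise is white.

**Fragmentation** (`n_submovements > 1`) is modelled as repeated partial
open–close attempts separated by a hesitation interval (0.25 s, stretched
to 0.45 T₀ at slow rates): the velocity stays zero-mean at the pair
timescale, so the 1 Hz drift high-pass does not ring into the rest
periods, while the per-movement speed profile acquires low-frequency
structure that the 0–4 Hz SPARC band sees. Hesitations also prolong the
cycle, so fragmented performances take longer — consistent with slow,
hesitant tapping. An earlier design that spread same-sign submovement
pulses across a longer phase produced sub-1 Hz velocity lobes whose
high-pass ringing merged adjacent cycles, and was rejected.

**Rigidity** is simulated as 0.5 Hz passive flexion-extension cycle pairs
with brisker pulses (σ = T₀/30, centres 0.15 T₀ apart) so their spectral
content clears the 1 Hz high-pass, and cogwheel is an amplitude modulation
of the velocity at 7.5 Hz whose depth is `min(0.2 · (severity), 0.9)` for
severity = `n_submovements − 1`. Severity 0 recordings stay closest to the
smooth single-pulse SPARC reference; deeper modulation is strictly more
negative.

**Cohort defaults.** The clinical study the design mirrors reports group
statistics but no waveform-level parameters, so the group distributions are
modelling choices, calibrated once so the simulated contrasts reproduce the
scale of the reported effect statistics (paired/mixed F in the teens to
thirties at n = 12/13 for total power; post hoc index-finger p ≤ 0.001):
OFF 100 ± 15 deg/s peak with decay −3 ± 0.7 deg/s per cycle, 1.5 Hz, 15%
interval jitter, 3 submovements, 3 deg/s tremor; ON 260 ± 30, −1.5 ± 0.5,
2 Hz, 8%, 2 submovements; healthy 320 ± 30, −0.5 ± 0.3, 2.5 Hz, 3%,
1 submovement, no tremor. Each PD subject carries a lognormal amplitude
factor (cv 0.1) shared between OFF and ON, inducing the within-subject
pairing; per-location amplitude scaling (index 1, thumb 0.8, metacarpus
0.55, wrist 0.4, arm 0.2) makes distal sensors the most informative, and
decay and tremor scale along with it so relative decrement is
location-invariant.

**What the generator does not emulate.** Gravity and linear-acceleration
content (accelerometers carry noise only), magnetometer data, sensor
misalignment, goal-directed variability in movement direction, and strong
rest tremor: a tremor comparable to the movement amplitude keeps the
broadband speed profile above the 10% threshold throughout, which defeats
threshold segmentation on the drift-removed profile — real tremor-dominant
recordings would need band-limited segmentation first. Passing tests on
synthetic cohorts therefore demonstrates the correctness and calibration of
the analysis chain, not its robustness to every artifact of real
recordings.

## Problem sizes used by the tests

The suite verifies segmentation exactness over rates {1, 2, 3} Hz and
amplitudes {20, 300} deg/s, statistical calibration with 500 null
replicates per test (type-I error required within [0.03, 0.07] at α =
0.05), and end-to-end discrimination on 200 replicate cohorts of 12 PD +
13 healthy subjects at the index finger, requiring the OFF/ON and
OFF/healthy total-power contrasts to be flagged at the 0.01 Bonferroni
threshold in at least 80% of replicates. ANOVA F statistics are checked
against hand-written sums-of-squares decompositions to 1e-8, SPARC against
an independent direct-DFT arc-length oracle to 1e-8, and the normality
screen against reference Shapiro-Wilk values to 1e-6.

## Known limitations

* The 10%-of-peak rule presumes the speed returns near zero between
  cycles; continuous or tremor-superimposed movement violates this.
* Sphericity is not corrected by default; with five locations the
  within-subject covariance structure may call for Greenhouse-Geisser
  correction on real data.
* Total power is reported for the task axis by default; a `sum3` policy is
  available but changes the scale.
* The distinction between a movement "cycle" and a "single movement"
  (open vs close sub-phase) is not operationalised separately: per-cycle
  SAL is computed on whole cycles, which the merge rule treats as the unit
  of repetition.
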