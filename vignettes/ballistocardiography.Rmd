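---
title: "Heart beats from accelerometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart beats from accelerometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7, fig.height = 3)
library(accelbcg)
```

## The signal and the problem

Every heart beat ejects blood into the great vessels and the body recoils.
A sensitive accelerometer fixed to the body records that recoil — the
ballistocardiogram (BCG). In bio-logging, animal-borne inertial tags
already carry such accelerometers, so in principle heart beats can be read
from archived tag deployments without any dedicated cardiac hardware. In
practice the cardiac signal is tiny, buried in locomotion, swell, and
sensor noise, and only interpretable when the animal is not moving.

`accelbcg` implements a detection pipeline for this setting, aimed at
large diving mammals: the recoil wave packet is strongest along the
cranio-caudal (surge) axis, carries its power in the few-Hz band (in
humans the IJK complex concentrates between 4 and 7 Hz), and recurs at
apneic heart rates that can be as low as 4–8 beats min⁻¹ in the largest
divers. Everything downstream — validation against ECG, spectral
signal-to-noise, diving bradycardia trends — is standard statistics, and
the package wires those analyses to the detector.

## The four-stage pipeline

`compute_bcg()` composes four stages. All windowed operations share a
single window length $w$ (`window_s`), the method's main tuning knob.

1. **Band-pass filter** (`bcg_bandpass()`): 5th-order Butterworth,
   applied forward and backward (`signal::filtfilt`), per axis. The 1 Hz
   lower corner removes drift and swell; the upper corner (25 Hz or 10 Hz
   depending on preset) removes broadband noise above the beat waveform.
   Forward–backward filtering contributes no phase lag. The original
   description does not say whether filtering was zero-phase; we commit to
   zero-phase because every downstream use — pairing detected beats with
   ECG R-times, assigning heart rates to dive phases — depends on beat
   *timing*, and a one-pass IIR filter would delay peaks by a
   frequency-dependent amount.
2. **Savitzky–Golay differencing** (`bcg_sg_difference()`): a local
   polynomial of order 4 is fitted over an odd window of
   `round(w * fs)` samples and its first derivative evaluated per sample
   — a *smoothed first difference*, in units per sample step. It is
   deliberately not divided by the sampling interval: the output
   exaggerates peak structure (the J wave) and is not an estimate of jerk.
3. **Shannon-entropy fusion** (`bcg_entropy()`): each axis is rescaled so
   its largest absolute value in the analysis segment is 1, then
   $H_i = -\sum_k |a_{ik}|\,\ln |a_{ik}|$ with $0\ln 0 := 0$, where $k$
   runs over surge only (1d mode) or surge, sway and heave (3d mode).
   The transform is nonnegative for $|a| \le 1$ and peaks at $|a| = 1/e$:
   it lifts mid-amplitude beat structure while flattening the small-noise
   floor and isolated full-scale spikes. The rescaling is what guarantees
   nonnegativity, and it makes the whole pipeline invariant to the input's
   amplitude units (g versus m s⁻²; a tested invariant). We rescale by
   the per-segment maximum — the per-window alternative would make the
   BCG discontinuous at window joins.
4. **Triangular smoothing** (`bcg_tma()`): two passes of a centered
   simple moving average of `ceiling(n/2)` samples (odd-forced), which is
   exactly a triangular-weighted average of total support ≈ `n`. Center
   weighting removes residual jitter while keeping peaks sharper than a
   flat average of the same support.

Centered filters need data on both sides; we extend the record by odd
reflection at both ends, and the first and last $w$ seconds of the BCG are
flagged (`edge` column) so users can down-weight them.

### Window presets

Two presets mirror the parameterizations used on real deployments:
`killer_whale` (0.5 s window, 1–25 Hz, i.e. 200 samples at 400 Hz) and
`blue_whale` (2.0 s window, 1–10 Hz, 800 samples at 400 Hz). The window
should match the *width of the beat waveform*, not the heart rate: the
Savitzky–Golay stage fits a quartic across the whole window, so a window
much wider than the wave packet averages the oscillation away (a 2 s
window suppresses a 5 Hz carrier almost entirely, leaving only flank
artifacts). Larger animals have slower, wider waveforms, hence longer
windows; but a slow *heart rate* with a fast waveform still wants a short
window. Simulated records use the 5 Hz default packet, so analyses of
simulator output in this package use the 0.5 s window even at 6 beats
min⁻¹.

## Beat detection by height–prominence clustering

`find_candidate_peaks()` extracts every local maximum of the BCG and
greedily prunes by descending height so survivors are at least one window
apart (ties keep the earlier peak — determinism matters for reproducible
runs). For each survivor we compute topographic prominence: height above
the lowest valley separating the peak from higher neighbors, with record
edges acting as higher neighbors; the global maximum's prominence is its
height above the global minimum. A brute-force scan over the definition is
the oracle for both in the test suite.

`cluster_peaks()` computes each peak's Euclidean distance from the highest
peak in raw (height, prominence) coordinates — both share BCG units, so we
do not standardize — and estimates the density of those distances
(Gaussian kernel, Silverman bandwidth, 512 points on [0, max]). On real
and simulated records this density is bimodal: beat peaks cluster near the
reference, noise peaks far from it. The threshold is the valley of the
density: we place it at the local minimum with the greatest depth below
the smaller of its flanking maxima, and require that minimum to dip below
75% of both flanks. This is equivalent to "the valley between the two
modes" when the density is cleanly bimodal, but does not get distracted by
small wiggles riding on one cluster. A valid split must also leave at
least two peaks on each side — one point is not a cluster. If no such
valley exists (fewer than 3 peaks, zero spread, effectively unimodal
density) every peak is accepted and a `degenerate` flag is set rather
than silently rejecting anything.

`instantaneous_hr()` converts accepted beats to rates, one per inter-beat
interval, assigned to the interval midpoint — an unbiased placement for
regressing rate against time.

## Behavioral gating

The BCG is only readable when the body is still. `segment_dives()` marks
maximal intervals deeper than 2 m (boundaries linearly interpolated to
sub-sample precision) and retains dives exceeding 10 m depth and 5 min
duration — all strict inequalities, read literally from their definitions.
`find_motionless()` rectifies lateral-axis gyroscope rotational velocity
(fluke strokes are conspicuous there, and the gyroscope is a separate
sensor from the accelerometer being analyzed), smooths it with a centered
moving average (default 5 s), and keeps sub-threshold stretches of at
least `min_dur_s`, trimmed by one smoothing window at each end. The
default threshold is record-relative with a physical cap:
`min(4 × q10, 0.1 rad/s)`, where `q10` is the 10th percentile of the
smoothed envelope. The percentile anchors the quiet floor whatever the
tag's noise figure; the fixed factor 4 provides headroom above that floor
while staying one to two orders of magnitude below stroking amplitudes. A
threshold placed *at* a percentile cannot work (it keeps that percentile
of samples by construction), and a purely record-relative rule cannot
reject a record that strokes throughout — its own quiet floor is the
stroking level — hence the absolute ceiling, set well above genuine
motionless rotational velocities and well below fluke strokes (override
it for tags reporting deg/s). Any numeric criterion here is a surrogate
for expert visual stroke marking; the threshold is exposed for override.

## Validation statistics

* `ols_equivalence()` pairs BCG- and ECG-derived instantaneous heart
  rates by nearest interval midpoint (one-to-one, closest first, within
  `window_s` by default) and regresses BCG on ECG rate. Equivalence means
  failing to reject intercept = 0 and slope = 1 (two-sided t-tests), and
  the mean ± s.d. absolute percent error summarizes agreement on the
  original scale.
* `bcg_snr()` integrates a Welch power spectral density (Hann taper, 50%
  overlap, per-segment linear detrending, 60 s segments by default) over
  the expected heart-rate band — 4–8 beats min⁻¹ for apneic large whales —
  and divides by the integral of the remainder up to 60 beats min⁻¹,
  starting at the lowest resolved frequency (DC is meaningless after
  detrending). Windows shorter than four periods of the band floor (60 s
  for 4 beats min⁻¹) are refused. A flat spectrum gives SNR ≈ 4/52, the
  ratio of band widths; this closed form anchors the estimator's tests.
  Welch is the package's PSD estimator throughout.
* `theil_sen_trend()` fits slope = median of all pairwise slopes and
  intercept = median of residuals, robust to the outliers (premature
  beats) and heteroscedasticity typical of diving heart-rate profiles; the
  one-sided p-value for a rising trend comes from the Kendall rank
  correlation test, the classical companion of the Theil–Sen estimator.
  `dive_phase_profile()` maps heart-rate points into normalized dive time
  (0 = dive start, 1 = end), pools retained dives, and reports the fitted
  rate at both ends of the dive.

## The simulator: what it emulates, and what it does not

`simulate_record()` generates the joint structure the method assumes:

* **Beat packets**: Gaussian-enveloped sinusoids at 5 Hz (center of the
  human IJK band; no marine-mammal waveform spectrum has been published)
  with a 0.1 s envelope, strongest on surge (weights 1/0.4/0.3), at
  0.05 g peak — chest-wall cardiac vibration recorded by a body-mounted
  accelerometer is a tens-of-milli-g signal, and the regime in which the
  method was demonstrated on real whales shows packets clearly above the
  noise floor in band-passed traces.
* **Noise and drift**: white noise at 0.004 g r.m.s. (the wideband floor
  of a 300 µg/√Hz MEMS accelerometer sampled at 400 Hz) plus 0.05 g of
  0.05 Hz drift standing in for swell and respiration.
* **Heart-rate profiles**: constant (default 6 beats min⁻¹, mid apneic
  range) or a 4 → 8 beats min⁻¹ ramp over each dive with a half-cycle
  phase offset at the record start; optional multiplicative interval
  jitter (`hrv_sd`) emulates sinus variability, without which a
  constant-rate record gives the equivalence regression nothing to fit.
* **Behavior**: trapezoidal dives with stroking descents, ascents and
  surface intervals (0.25 Hz artifacts on both sensors, dominant on the
  gyroscope lateral axis) and motionless bottom phases.
* **Reference ECG**: an idealized beat-time list equal to the truth —
  equivalence testing needs R-wave times, not an ECG waveform.

It does **not** model realistic BCG morphology (I/J/K sub-waves,
respiratory amplitude modulation), posture-dependent axis mixing,
tag-attachment resonance, or non-stationary noise. Passing the recovery
tests therefore shows the pipeline recovers beats whose statistical
structure matches its assumptions — it does not certify performance on
any particular real deployment, where waveform shape and artifact
structure must be inspected.

## Numerical choices and degenerate inputs

* Window counts are `round(window_s × fs)`, forced odd for symmetric
  filters; the presets reproduce 200 and 800 samples at 400 Hz.
* Non-finite samples: rejected by default; runs of ≤ 2 samples may be
  linearly interpolated on request. Filters assume contiguous data.
* Flat signals yield zero peaks; fewer than two beats yield an empty
  heart-rate series; fewer than three paired rates or a zero-variance
  reference abort the equivalence fit with typed errors; all-identical
  x aborts the trend fit. A record with no motionless windows aborts the
  field workflow with an explicit movement-artifact diagnostic.
* Sampling rates below 50 Hz trigger a warning (not an error): 50 Hz is
  twice the upper corner of the widest preset band, and beat waveforms
  ride at several Hz.
* Seeds: one integer seed drives the whole simulator; beat-time jitter
  draws from a seed stream derived from it so `simulate_beats()` and
  `simulate_record()` agree. Identical seed and configuration give
  bit-identical records and, the pipeline being deterministic, byte-identical
  outputs.

## Problem sizes in the shipped tests

The test-suite and acceptance-script simulations use 20 records of 600 s
at 400 Hz for beat recovery, 1000 replicates of n = 50 paired rates for
regression calibration, 50 records of 240 s for the 3d-versus-1d
signal-to-noise comparison, and one 77-minute, 10-dive record for the
dive-phase trend — sizes at which every Monte-Carlo margin in the checks
is stable across seeds while the whole suite stays comfortably
interactive.

## A worked example

```{r example}
rec <- simulate_record(sim_config(fs = 200, duration_s = 300,
                                  hr_profile = hr_constant(50),
                                  hrv_sd = 0.05, seed = 1))
v <- run_validation(rec$accel, rec$ecg_beats)
v$equivalence
tidy(v$equivalence)
```

```{r example-plots}
autoplot(v$equivalence)
autoplot(compute_bcg(rec$accel, bcg_config("killer_whale", axes_mode = "3d")),
         beats = v$beats) + ggplot2::coord_cartesian(xlim = c(60, 90))
```

## Known limitations

* The clustering assumes beat and noise peaks separate in
  height–prominence space; slow amplitude fades (tag slipping) can smear
  the modes together. The `degenerate` flag reports when no separation was
  found, but a *wrong* bimodal split is silent.
* Per-segment entropy normalization couples the BCG's shape to the
  segment's largest excursion; a single uncorrected artifact spike inside
  a motionless window rescales everything else in that window.
* Heart rates are only measured inside motionless windows, so dive-phase
  trends extrapolate through the stroking descent/ascent phases they
  cannot observe.
* The one-sided trend p-value tests monotone association (Kendall), not
  the Theil–Sen slope's own sampling distribution; with strong serial
  correlation in heart rate it is anti-conservative.
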