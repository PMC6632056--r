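---
title: "Estimating ankle joint power from two IMUs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating ankle joint power from two IMUs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Sagittal ankle joint power — the product of ankle joint moment and angular
velocity, normalised by body mass (w/kg) — is a clinically useful gait
index: the positive burst near the end of stance ("push-off", typically at
55–61% of the gait cycle) propels the body forward, and its amplitude and
timing degrade in ageing and neurological impairment. The reference way to
measure it is inverse dynamics over optical motion capture plus a
force-plate-instrumented treadmill, which confines measurement to the lab.

`imupower` estimates this power trace from two wearable inertial
measurement units only, one on the foot and one on the shank. The twelve
raw channels (3-axis accelerometer and gyroscope per segment) are not
converted to joint angles; the pipeline instead learns a direct regression
from windowed signal features to the instantaneous power value, and applies
a quantile-based post-hoc calibration that restores the peak amplitudes a
median regression systematically underestimates.

## Pipeline

1. **Smoothing.** Each IMU channel is passed through a 5-sample running
   median (`median_filter()`), which suppresses impulsive sensor artefacts
   without blurring the push-off transient. At the series edges the window
   shrinks symmetrically to the largest odd size available, so output
   length equals input length and the first/last samples pass through; the
   filter is idempotent on monotone series. A zero-phase 4th-order
   Butterworth low-pass at 6 Hz (`butterworth_lowpass()`) is available for
   smoothing the reference power trace, the conventional setting for gait
   kinematics; it is implemented as forward–backward filtering with
   odd-reflection padding and steady-state initial conditions so that DC
   gain is exactly 1 (a plain forward–backward pass without these
   precautions shows large edge transients).

2. **Features.** A 110-ms window (11 samples at 100 Hz, forced odd) slides
   over every channel with stride 1, and 13 time-domain descriptors
   established in EMG pattern recognition are computed per window: RMS,
   SAV, MAV, VAR, WL, SSC, SSI, a Daubechies-7 wavelet feature, DASDV,
   AAC, the log detector, and the slope and leading quadratic coefficient
   of least-squares line/parabola fits (`extract_window_features()`).
   Concatenating the 12 channels gives 156 columns per window, aligned to
   the window-centre sample.

   Choices worth stating explicitly:

   * *MAV* is computed as mean absolute value (SAV/N), the standard EMG
     definition, keeping the identity SAV = N·MAV exact; mean absolute
     deviation about the window mean is available via
     `mav_mode = "about_mean"`.
   * The *wavelet feature* is the mean absolute level-1 detail coefficient
     of a db7 discrete wavelet transform with half-sample symmetric
     extension — the only single-number db7 summary consistent with common
     EMG-feature usage. The 14-tap decomposition filter is hardcoded to
     full double precision and the transform was verified coefficient-level
     against an independent wavelet library; deeper levels are available
     via `db7_level`.
   * *SSC* counts strict sign changes of successive differences (zero
     threshold by default; a magnitude threshold is exposed).
   * *VAR* uses the N−1 denominator; *LF*/*PF* report slope and leading
     coefficient only, since intercepts duplicate the window mean.

3. **Scaling.** Features are min-max scaled to [0, 1] per column. The
   scaling is fit on the training rows only and applied unchanged to test
   data — test values may fall outside [0, 1] and are deliberately not
   clipped, because clipping would discard the very extrapolation signal
   the forest uses near peaks. Constant columns are flagged and map to 0.

4. **Quantile regression forest.** 50 regression trees are grown on
   bootstrap samples with `ceiling(p/3)` candidate features per split and a
   minimum terminal-node size of 5 (tree depth otherwise unbounded). Every
   leaf retains its in-bag training responses. A prediction at quantile q
   pools the responses of the leaf reached in each tree, weighting each
   response by 1/(n_trees × leaf size), and returns the weighted empirical
   quantile with linear interpolation; with equal weights this reduces
   exactly to the standard type-7 quantile, and q = 0/1 return the pooled
   minimum/maximum. q = 0.5 is the raw (uncalibrated) prediction. A
   simpler candidate set — one mean response per tree — is available via
   `candidates = "trees"`. Forest growing is delegated to `ranger`
   (single-threaded and seeded, so training is fully deterministic); the
   leaf bookkeeping and quantile machinery are this package's own.

5. **Quantile-probability calibration.** The raw median prediction
   underestimates power extremes, because the conditional median shrinks
   towards the bulk of each leaf's responses. The calibration records the
   minimum and maximum raw prediction over a calibration segment (the
   first half of each test trial), min-max normalises every subsequent raw
   prediction by these extrema, clips to [0, 1], and uses the result as
   the quantile probability of that row's own prediction: a raw value 75%
   up the calibration range selects the 75th percentile of its candidate
   distribution. Peaks are thereby pushed towards high quantiles and
   valleys towards low ones; calibrated peaks are never below raw peaks,
   calibrated valleys never above raw valleys. The extrema default to
   *predicted* power (deployment needs no reference instrumentation);
   `calibration_source = "reference"` reproduces the alternative reading.
   Clipping is required because the normalised value must be a
   probability; out-of-range raw predictions therefore saturate at the
   pooled extremes.

## Evaluation protocols

Gait cycles are delimited by the vertical GRF rising above 0 N, with a
100-ms debounce (`min_stance = 10` samples) because measured force plates
chatter around zero; the debounce is a package choice exposed in the
config. Spans are half-open 1-based intervals `[start, end)`; the trailing
partial cycle is dropped.

* **Intra-subject:** per subject, train on the first half of every trial,
  then use the first half of each test half for calibration and score the
  remainder. Restricting scoring to the post-calibration span (the
  default, `eval_span = "second_half"`) keeps calibration and scoring data
  disjoint in both protocols.
* **Inter-subject:** leave one subject out, train on all trials of the
  rest, calibrate on the first half of each held-out trial and score its
  second half.

Reported per subject × speed cell and aggregated as unweighted means:
Pearson R, RMSE (w/kg), NRMSE, per-cycle mean peak power and its
occurrence (% of cycle, first-index tie-break, degenerate constant cycles
flagged and excluded from occurrence means), and the relative peak error —
peak difference divided by the reference range of the scored span. The
NRMSE denominator is the reference range over the scored span by default
(`nrmse_denominator` also offers `mean` and `max`); the range
normalisation is what reconciles RMSEs of a few hundredths of a w/kg with
NRMSEs of ~1% on traces spanning several w/kg. The relative peak error
divides mean peak difference by the cell's reference range; averaging
per-cell ratios versus dividing averaged errors by averaged ranges give
slightly different numbers, and both can be computed from the per-cell
table.

Training-set provenance is tracked: a model records the subject ids it was
trained on, and the leave-one-subject-out driver asserts the held-out
subject is absent.

## The synthetic cohort

No public dataset pairs dual-IMU recordings with reference ankle power, so
the package ships a seeded simulator whose defaults mirror the study
layout this method targets: 9 subjects × 5 treadmill speeds (0.4–1.6 m/s)
× 60-s trials at 100 Hz.

* **Power template.** One cycle is a positive Gaussian burst (push-off) at
  the speed-interpolated peak occurrence plus a negative Gaussian dip at
  mid-stance, returning to ~0 in late swing. Peak power, valley-to-peak
  range and peak occurrence at the five speeds follow normative anchor
  values (peaks 0.34–3.04 w/kg, occurrence 60.7%→54.8%, peaks arriving
  earlier as speed grows) and interpolate linearly in between.
* **GRF.** A double-bump stance curve, strictly positive throughout stance
  (~60% of the cycle) and exactly zero in swing, so threshold-0
  segmentation recovers the constructed cycles.
* **IMU channels.** Each channel is a band-limited periodic function of
  gait phase: six Fourier harmonics, dominated by the stride fundamental
  with a channel-specific phase lag spread around the circle — as
  foot/shank kinematics are dominated by the stride cycle with
  segment-specific lags. The quadrature structure embeds gait phase
  injectively across the 12 channels, which is what makes phase (and hence
  power) decodable from windowed features even for subjects whose
  higher-harmonic content differs. Channel amplitude scales with speed in
  proportion to the normative power range, carrying the speed cue a real
  sensor would carry. Channel units are arbitrary (unit scale): no
  physiological amplitude statistics were available, and none should be
  read into them.
* **Subject variability.** Each subject has one multiplicative power
  amplitude factor (log-normal, sd(log) = 0.1) — reproducing the
  observation that power amplitude varies substantially between
  individuals, and deliberately *not* echoed in the IMU channels, so
  amplitude transfer is a genuine inter-subject difficulty — plus seeded
  log-normal perturbations (sd(log) = 0.08) of the harmonic amplitudes
  and Gaussian phase shifts (sd = 0.1 rad) of the base waveforms. The
  perturbation magnitudes were chosen so that a held-out subject remains
  decodable by a model trained on others, which is the simulator's stated
  purpose; larger morphology jitter makes leave-one-subject-out fail not
  gradually but through isolated phase-aliasing spikes.
* **Cycle timing.** Cycle duration defaults to 1.4 s at 0.4 m/s falling
  linearly to 1.0 s at 1.6 m/s (plausible adult cadence), jittered
  uniformly by up to ±3% per cycle.
* **Noise.** Independent Gaussian noise per channel, default
  `noise_sd = 0.1` — about 10% of the unit-scale channel amplitude.

What the simulator does **not** emulate: gravity components and sensor
orientation drift, soft-tissue artefact, impact transients at heel strike,
asymmetric or pathological gait, step-to-step waveform variability beyond
duration jitter, and any physical (inverse-dynamics) consistency between
channels and power. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's machinery is correct and that it recovers
a learnable phase-coded signal-to-power mapping — not that a given
accuracy will be attained on real recordings.

## Problem sizes and determinism

The test suite and the acceptance script run cohort-scale checks at sizes
chosen to finish comfortably on a single CPU: the full-protocol check uses
the 9-subject × 5-speed layout with 20-s trials and, for the
leave-one-subject-out folds, a training-row stride of 5 (prediction is
always dense; `train_stride` thins training rows only). Noiseless
learnability checks use 1–3 subjects with 20–30-s trials. All randomness —
simulation, bootstrap, feature subsetting — flows from explicit seeds, and
identical seeds yield bit-identical cohorts, trial files, model
predictions and evaluation reports.

## Known limitations

* The forest cannot extrapolate beyond the convex hull of its training
  responses: a held-out subject whose power amplitude exceeds every
  training subject's saturates at the pooled maximum even after
  calibration.
* The calibration's extreme quantiles (q near 0 or 1) are order
  statistics of the pooled leaf responses and are sensitive to a single
  stray tree when training data are sparse; short calibration segments
  can therefore overshoot peaks at slow speeds, where the power range is
  narrowest.
* Per-sample quantile selection assumes the calibration segment spans the
  same dynamic range as the scored segment; a calibration segment missing
  a representative peak compresses the mapping.
* The 110-ms window bounds the temporal resolution of the estimate; power
  transients shorter than the window are smoothed.
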