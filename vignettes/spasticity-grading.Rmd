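---
title: "Grading elbow spasticity from inertial passive-stretch recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading elbow spasticity from inertial passive-stretch recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spastimu)
```

## The problem

Spasticity is a velocity-dependent increase in muscle tone during passive
stretch, common after stroke, spinal cord injury and cerebral palsy. In the
clinic it is graded on the modified Ashworth scale (MAS), a six-level ordinal
scale `0, 1, 1+, 2, 3, 4`: an examiner moves the relaxed limb through its
range of motion and rates the resistance felt, from no increase in tone (0),
through a transient *catch* with or without sustained resistance (1, 1+, 2),
to movement that is difficult (3) or a limb rigid in flexion and extension
(4). The rating is cheap but subjective, with well-documented inter-rater
reliability problems, particularly between grades 1 and 1+.

`spastimu` implements a sensor-based alternative for the elbow: during a
standard passive stretch manoeuvre — a quasi-static hold, then five
flexion–extension cycles at one cycle per second — a forearm-mounted inertial
measurement unit records triaxial acceleration (in g) and angular velocity
(in deg/s) at 256 Hz. The recording is reduced to features, and supervised
classifiers trained on therapist-rated recordings assign one of the six MAS
grades, treated as nominal classes (the `1+` level breaks the case for an
ordinal treatment). The package covers the full pipeline: signal simulation,
preprocessing, windowing, feature extraction, cross-validated evaluation of
five classifier families, and the statistical comparison of the design
choices.

## The synthetic cohort generator

No public corpus of labeled passive-stretch IMU recordings exists, so the
package ships a generative model of the manoeuvre
(`simulate_angle_trajectory()`, `angle_to_imu()`, `simulate_cohort()`). It is
a *phenomenological* model: its purpose is to produce signals with the
statistical structure the analysis pipeline assumes, not a biomechanically
validated simulation.

* **Kinematics.** The elbow angle follows a raised-cosine half-cycle from
  full flexion (0°) to the grade's range of motion (ROM) and back, repeated
  `n_cycles = 5` times at `cycle_period_s = 1`, between 1 s quasi-static
  holds, sampled at 256 Hz (7 s, 1792 samples per recording).
* **Grade effects.** Severity acts through two per-grade parameter vectors.
  The excursion `rom_deg` (defaults 120/110/100/80/50/8°) shrinks with grade
  until near-rigidity at MAS 4, and the extension half-cycle passes through a
  *catch*: angular velocity is transiently multiplied by
  `1 − catch_depth · exp(−½((θ/ROM − c)/ (w/2))²)`, a Gaussian notch of depth
  `catch_depth` (defaults 0/0.35/0.5/0.65/0.8/0.9) centred at fraction
  `catch_angle_frac` of the excursion with width `catch_width_frac`. The notch
  is applied as a time warp that preserves the half-cycle duration — the
  examiner pushes through the resistance and completes the cycle on pace — so
  its practical effect is a localized slow-down with a compensating speed-up
  elsewhere. Low grades get narrow notches (a transient catch-and-release);
  mid grades wider ones (resistance through part of the ROM). With zero
  noise, the minimum extension-phase angular speed is non-increasing in the
  MAS label, which is the velocity-dependent phenomenology the scale
  describes and is verified as a property test.
* **Sensor model.** A single-axis rotation: gyroscope x reads the angle's
  first difference times the sample rate; the accelerometer reads gravity
  rotated through the elbow angle (`ay = sin θ`, `az = cos θ` in g), so the
  roll angle recomputed from noiseless acceleration recovers the joint angle.
  The device carries a magnetometer in practice, but no feature uses it, so
  it is not simulated. Measurement noise is i.i.d. Gaussian per axis
  (defaults 0.01 g and 1 deg/s — typical consumer-IMU figures at this rate);
  between-subject variability jitters each subject's ROM (±5% s.d.) and catch
  depth (±0.03 s.d.).

What the generator does **not** emulate: therapist hand-speed variability and
inter-rater label noise, voluntary or reflex muscle activity, sensor
misalignment and soft-tissue artefact, and any coupling between axes beyond
the single-axis rotation. Tests passing on synthetic cohorts therefore
validate the pipeline's mechanics and its sensitivity to the modeled grade
effects — they do not certify clinical accuracy on real patients.

`easy_regime_config()` is a second, deliberately well-separated
parameterization (catch depths spaced by ≈0.2, widths growing with grade,
tight jitter) used for parameter-recovery validation: when the six grades are
clearly distinct in the generating process, the pipeline should recover them
almost perfectly, and it does (≈98% leave-one-subject-out accuracy for the
random forest on the 58-feature set; the singleton MAS 4 class is excluded
from the score because leave-one-subject-out can never train on it). The
`simulation_config()` defaults keep the harder, clinically more plausible
narrow low-grade catches, under which adjacent low grades genuinely overlap.

## Preprocessing

`trim_baseline()` discards the quasi-static holds using the gyroscope vector
magnitude: the retained interval is the hull of all runs of at least
`min_active_s = 0.25` s whose magnitude stays at or above
`gyro_threshold_dps = 10` deg/s. The defaults separate the hold (noise
magnitude ≈ 2 deg/s) from the 1 Hz stretch (peak speeds in the hundreds of
deg/s) by an order of magnitude in both directions; the debounce keeps short
noise bursts from extending the interval. A recording with no qualifying run
raises a "no movement detected" error naming the threshold.

`extract_middle_cycles()` then divides the active interval of length `L` into
five equal blocks of `floor(L/5)` samples and keeps blocks 2–4 — the middle
three of the five cycles, the most stable part of the manoeuvre. Blocks are
index blocks, not detected cycles: the protocol fixes five cycles, so equal
division is the faithful (and deterministic) reading. All indices in the
package are 0-based, half-open.

## Segmentation: DS1 and DS2

Each three-cycle portion is windowed two ways (`build_segment_table()`):

* `nonoverlap` (dataset **DS1**): three windows of `w = floor(L/3)` samples
  at offsets `0, w, 2w` — 3 segments per recording;
* `overlap50` (**DS2**): five windows of `w` samples with hop
  `h = floor(w/2)` at offsets `0, h, …, 4h` — 5 segments per recording,
  consecutive windows sharing `w − h` samples.

For odd `w` the hop is `floor(w/2)`, so "half the samples" holds to integer
precision; trailing remainders are discarded, never padded (padding would
distort the spectral features). For the reference 48-subject cohort
composition (17/13/7/6/4/1 across grades) this yields 144 DS1 segments
(51/39/21/18/12/3 per grade) and 240 DS2 segments.

## Features: FS1 and FS2

`featurize()` computes, per window:

* **FS1** (42): seven statistics — root mean square, mean, standard
  deviation, energy, spectral energy, absolute difference, variance — on each
  of the six raw channels. Moments are population moments
  (denominator `n`). *Energy* is the mean square `Σx²/n`; *spectral energy*
  is the Parseval-normalized DFT energy `Σ|X_k|²/n²`, mathematically equal to
  the energy and retained as a numerical cross-check feature so the seven-
  statistic list is mirrored verbatim; *absolute difference* is the mean
  absolute successive difference, the standard roughness feature in activity
  recognition (the alternative reading, mean absolute deviation from the
  mean, was considered and rejected as redundant with the standard
  deviation).
* **FS2** (58 = 42 + 16): the same seven statistics on the per-sample roll
  `(180/π)·atan2(a_y, a_z)` and pitch `(180/π)·atan2(a_x, a_z)` series —
  computed from raw acceleration with no gravity-separation filter, since
  gravity dominates during slow passive stretch — plus the signal magnitude
  area `SMA = Σ(|x_i|+|y_i|)/n` and signal vector magnitude
  `SV = Σ√(x_i²+y_i²)/n` of the accelerometer x/y axes. `atan2` is the
  quadrant-aware two-argument inverse tangent; the degenerate (0, 0) input
  returns 0 with a warning. `sv ≤ sma` always (triangle inequality); both
  are nonnegative.

Feature order is fixed (channel-major, then statistic; `feature_names()`), so
feature matrices are reproducible column-for-column.

## Classification and evaluation

`loocv()` evaluates `DT, RF, SVM, LDA, MLP` under leave-one-out
cross-validation. The held-out unit defaults to the **subject**: with 50%
overlap, adjacent windows of one subject are near-duplicates, and
segment-level folds would leak them between training and test, so
leave-one-subject-out is the defensible default; segment-level folds remain
available (`granularity = "segment"`) for comparison with protocols that
windowed first and split later. Features are z-scored with statistics fit on
the training fold only, applied to the held-out fold, for the scale-sensitive
families (SVM, LDA, MLP).

Hyperparameters are fixed and documented (`classifier_control()`), never
tuned: an unpruned `rpart` tree; 100-tree random forest; RBF-kernel SVM at
cost 1 with e1071's native one-versus-one multiclass decomposition; plain
LDA; and a single-hidden-layer perceptron of 16 units, weight decay 0.01,
trained to convergence without early stopping — with only 100–250 training
segments a wider layer is over-parameterized and slower for no accuracy
gain. All stochastic fits are seeded per fold, so every result in the package
is a pure function of the root seed.

Folds whose training set lacks a class are permitted and recorded
(`folds_missing_class`); with one MAS 4 subject this is unavoidable under
leave-one-subject-out, and that class is excluded from recovery scoring.
A fold whose training set collapses to a single class predicts that class.

Accuracy is the match fraction; `per_class_metrics()` reports precision,
recall and their mean as a per-class accuracy, with undefined ratios reported
as `NA`, never 0. `run_condition_grid()` runs all 2 × 2 × 5 = 20
dataset/feature-set/classifier conditions and aggregates median accuracies
per cell, per feature set, per dataset and per classifier, then compares FS1
vs FS2 and DS1 vs DS2 with paired two-sided Wilcoxon signed-rank tests at
α = 0.05, paired over the non-compared factors (10 pairs each), raw p-values
without multiplicity correction (flagged as such).

`wilcoxon_compare()` is implemented in the package: zero differences dropped,
average ranks on ties, exact two-sided p by convolution over the doubled
ranks (equivalent to enumerating all 2ⁿ sign assignments) for effective
n ≤ 25, tie-corrected normal approximation with the standardized statistic Z
otherwise; all-zero differences degenerate to p = 1 with a warning. Both
branches are cross-checked against `stats::wilcox.test` in the test suite.

## Numerical and design notes

* Problem sizes: validation experiments use the 48-subject reference cohort
  for single-grid and recovery runs, and ten matched 20-subject cohorts
  (6/5/3/3/2/1) for the segmentation-scheme comparison — enough to pin the
  direction of the overlap effect while keeping a full run in minutes on one
  core.
* The noise-robustness sweep scales both sensors together
  ({0.01, 0.05, 0.2} g with {1, 5, 20} deg/s): the forest can lean entirely
  on whichever sensor stays clean, so degrading one sensor alone mostly
  tests feature selection, not robustness.
* The trim threshold interacts with gyro noise: at noise s.d. ≥ ~5 deg/s the
  10 deg/s threshold no longer separates hold from motion for the near-rigid
  grade; raise `gyro_threshold_dps` accordingly if you re-parameterize noise
  upward.
* Known limitations: only 0% and 50% overlap are shipped; six nominal
  classes (no ordinal structure exploited); aggregate window statistics
  discard the catch's angular position, which a clinician uses; and the
  singleton-class fold issue above is inherent to leave-one-subject-out with
  a cohort containing a single MAS 4 subject.

## A worked run

```{r example, eval = FALSE}
cfg <- pipeline_config(
  cohort = c(`0` = 17, `1` = 13, `2` = 7, `3` = 6, `4` = 4, `5` = 1),
  seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

The report lists 144 DS1 and 240 DS2 segments, the 20 per-condition
accuracies with their medians, and the two paired Wilcoxon comparisons. The
same computation, quantity by quantity, is what `scripts/acceptance.R`
re-runs and serializes to JSON.
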