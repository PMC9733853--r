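---
title: "Methods: recognising line-worker tasks from a wrist accelerometer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognising line-worker tasks from a wrist accelerometer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristhar)
```

## The problem

Electrical line workers perform a small vocabulary of physically
demanding tasks — climbing ladders, hoisting buckets, lifting boxes,
working overhead or at an electrical panel — interleaved with ordinary
mobility (sitting, standing, walking) and desk work. A single
wrist-worn tri-axial accelerometer sampled at 32 Hz is an unobtrusive
way to monitor which task is being performed, a prerequisite for
workload and safety analytics. `wristhar` implements the complete
recognition pipeline: windowing, three feature domains, classifier
evaluation under two deployment scenarios, statistical model
comparison, and interpretation of what the classifiers rely on.

Because no raw recordings of this population are publicly deposited,
the package ships a synthetic-cohort generator whose ten task classes
carry the signal structure the method assumes. Every stage is
validated against that generator; the generator itself is first-class,
tested code.

## The synthetic cohort

Each task is generated as

\[ a(t) = R\,g + \sum_j R\,A_j \sin(2\pi f_j (1+\delta) t + \phi_j)
   + \varepsilon(t) + I(t), \]

where \(g\) is a unit gravity vector fixing the static wrist
orientation of the task, \(A_j, f_j, \phi_j\) are per-axis sinusoid
parameters, \(\varepsilon\) is per-axis Gaussian noise, and \(I\) is a
train of Poisson-timed one-sample spikes smoothed with a 5-sample Hann
kernel (emulating the abrupt transients of manual handling that the
wavelet features are designed to capture). \(R\) is a per-subject
device rotation and \(\delta\) a per-subject frequency jitter.
Acceleration is in units of g with |gravity| = 1, the wrist-device
convention.

Structural commitments of the default profiles:

* **Postural tasks** (sitting, standing, typing) are static with
  well-separated gravity orientations. Sitting and standing differ by
  more than 30 degrees, so time-domain *mean* features separate them
  even though the acceleration *magnitude* is ~1 g for both — the
  reason the pipeline uses per-axis rather than magnitude features.
* **Locomotion-like tasks** (walking, pushing, ladder) carry a
  dominant periodic component in the gait band (0.9–1.8 Hz) plus a
  harmonic.
* **Hoisting** has by far the largest noise dispersion, concentrated
  on the X axis, plus frequent impulses — a high-entropy class.
* **Electrical panel** concentrates both its static orientation and
  its dynamic content (0.8 Hz and 2.5 Hz components, impulses) on the
  Z axis. The interpretation stage must rediscover this Z-dominance
  from the fitted classifiers.

Session durations follow the study protocol: duration tasks run 3
minutes; repetition tasks are given a fixed per-repetition duration
(9 s per repetition for hoisting, lifting and pushing; 6 s for ladder
climbing), chosen so every task yields at least 9 windows at the 10 s
window length. The protocol reports repetition counts, not durations,
so these per-rep values are a documented stand-in, not an inference
about the original sessions.

Inter-subject heterogeneity uses `amp_scale ~ LogNormal(0, 0.15)`,
`freq_jitter ~ U(-0.15, 0.15)` and a device rotation of
`U(0°, 20°)` about a random axis. These spreads are wide enough that
generalising to unseen subjects is genuinely harder than
within-subject classification, without destroying class separability.
Setting all three to zero yields an idealised cohort in which the
intra- and inter-subject protocols must agree — a recovery property
the test suite asserts.

What the generator does **not** emulate: joint kinematics, fatigue
drift, intermittent/mixed task schedules, device re-positioning
mid-session, or sensor saturation. Passing tests therefore demonstrate
that the pipeline recovers structure the generator puts in — not field
performance on real workers.

## Windowing

Recordings are segmented into non-overlapping fixed-length windows of
4 s (128 samples) or 10 s (320 samples). Windows are anchored at each
annotation interval's start — not the recording start — which
guarantees label purity without change-point detection; interval
starts are rounded up to the next sample for deterministic indexing,
and trailing partial windows are discarded. Whether the original
analysis dropped or truncated boundary-crossing windows is not stated;
dropping is this package's documented assumption.

## Feature domains

* **Time (27):** each axis is low-pass filtered with an order-4
  Butterworth at 10 Hz (human wrist movement rarely exceeds 10 Hz) and
  summarised by 9 statistics: mean, RMS, mean absolute deviation,
  standard deviation (n−1), min, max, median, 25th and 75th
  percentiles (linear interpolation). The filter is applied in a
  single forward pass so the −3 dB point stays at the cutoff;
  start-up transients are absorbed by a discarded odd-reflection
  lead-in.
* **Frequency (120 / 300):** FFT magnitudes of the raw axis signals,
  keeping bins strictly below 10 Hz including DC — `10 × window_s`
  bins per axis, the only retention rule that matches both printed
  dimensions with a single formula. Magnitude (not power, not complex
  pairs) is used; this is the standard convention and matches the
  dimension counts.
* **Time-frequency (180 / 216):** db4 discrete wavelet transform at
  the maximum admissible depth (4 levels at 128 samples, 5 at 320),
  with periodized boundaries so band lengths halve exactly and the
  transform is orthogonal (perfect reconstruction to machine
  precision, asserted). Twelve descriptors per band — Shannon entropy
  of the normalised squared coefficients, strict zero- and
  mean-crossing counts, and the same 9 statistics — over the deepest
  approximation and all detail bands. Entropy and crossing definitions
  are not fixed by the source method and are documented choices here.

## Classification

Grids follow the study: k-NN over k ∈ {1, 4, …, 28}, Euclidean or
Manhattan distance, uniform or distance-weighted votes; SVM over C on
a log grid {0.01, 0.1, 1, 10, 50} (the study prints only the range
0.01–50) with linear/polynomial/RBF/sigmoid kernels; random forest
over max depth {5, 10, 20, 30, 40} and mtry {20, 30, 40, 50, 60},
with infeasible mtry candidates (e.g. >27 on the time features)
skipped rather than erroring. Tuning is exhaustive grid search scored
by mean accuracy over stratified 10-fold cross-validation; ties go to
the first candidate in grid order; the winner is refit on all
training rows.

Features are z-scored with training-partition statistics for k-NN and
SVM only — the source method does not mention scaling, but FFT and
wavelet features span orders of magnitude and distance/kernel methods
are scale-sensitive, while forests are scale-invariant. This is a
documented assumption. Multi-class SVM uses `e1071`'s pairwise
(one-vs-one) voting. All randomness flows from named seeds recorded
in the report.

The intra-subject protocol splits each subject 80/20 with per-class
test size `round(0.2 n)` (at least 1); the inter-subject protocol
partitions subjects into five balanced folds (37 subjects give
8, 8, 7, 7, 7). Reported metrics are unweighted means across subjects
or folds — whether the original analysis weighted by window count is
unstated; unweighted is this package's choice.

## Model comparison

A fixed-effects two-way ANOVA with interaction
(`accuracy ~ feature * classifier`) is run per window length on the
five inter-subject fold accuracies — the only replicate structure the
protocol exposes. The balanced design makes type I/II/III sums of
squares coincide; the suite checks the F statistics against a
definitional sums-of-squares oracle to 1e-10 and calibrates the
type-I error rate under a simulated null. Significant main effects
are followed by Tukey HSD using R's exact studentized range
distribution (`ptukey`).

## Interpretation

Overall importance is the random forest's normalised mean impurity
decrease. Class-specific importance fits a local surrogate per
correctly classified window (30 windows, following the study):
Gaussian perturbations in standardised feature space, exponential
kernel `exp(-d²/κ²)` with `κ = 0.75√d`, weighted ridge regression
(penalty 1) of the target-class score, selection of the largest
absolute coefficients (30 frequency / 15 time-frequency features),
and elementwise averaging of the signed weights. The surrogate's
hyperparameters are not fixed by the source method; the defaults
follow the original local-surrogate convention and are configurable.

One practical caveat the synthetic data exposes: k-NN vote shares are
piecewise constant, and on cleanly separated classes every local
perturbation keeps the same neighbours, so the surrogate sees a
constant function (the package flags this rather than returning
noise). The worked examples therefore explain the random forest's
smooth class probabilities; on noisier real data k-NN scores vary
locally and the method applies unchanged.

Reconstructions invert the transforms from which the features came:
selected frequency features keep their DFT bins (conjugate partners
added so the inverse is real, full selection is the identity);
selected wavelet features keep their whole source bands — the
features are band statistics, so "the coefficients the statistics
were derived from" is a band, not a single coefficient — and zero the
rest before the inverse transform.

## Problem sizes and numerical choices

The packaged validation runs use a 10-subject cohort at 10 s windows
with time-frequency features and a reduced forest grid
(depth {10, 20} × mtry {20, 40}, 200 trees) — large enough that the
intra ≥ 0.90 / inter ≥ 0.85 recovery thresholds are meaningful, small
enough to run on a laptop in minutes. Degenerate inputs are handled
explicitly: empty bands and all-zero windows yield zero features
(entropy of an all-zero band is defined as 0), zero-distance k-NN
neighbours take over the vote, constant surrogate outputs are
flagged, and sub-window annotation intervals produce warnings, not
errors.

## A worked run

```{r, eval = FALSE}
cfg <- cohort_config(n_subjects = 10, master_seed = 101)
cohort <- simulate_cohort(cfg)
wins <- unlist(lapply(cohort, function(s)
  segment_windows(s$recording, s$annotations, windowing_config(10))),
  recursive = FALSE)
fm <- build_feature_matrix(wins, "timefreq")

rf <- model_config("rf", grid = list(max_depth = c(10L, 20L),
                                     mtry = c(20L, 40L)),
                   num_trees = 200L, seed = 3)
intra <- intra_subject_eval(fm, rf, split_seed = 5)
inter <- inter_subject_eval(fm, rf, fold_seed = 5)

model <- tune_model(fm, rf)$model
rf_overall_importance(model, top_k = 15)
class_importance(model, fm, "electrical_panel", n_obs = 30,
                 cfg = lime_config(n_perturbations = 1000,
                                   n_selected = 15, seed = 11))
```

## Known limitations

* Synthetic validation only: thresholds met here say nothing about
  accuracy on real workers; the study's own headline numbers require
  its undeposited recordings.
* Entropy/crossing formulas, FFT magnitude convention, scaling
  policy, SVM grid discretisation, stratified rounding and replicate
  weighting are documented assumptions where the source method is
  silent.
* No overlapping/event-defined windows, no deep models, no streaming
  classification, no mixed task schedules.
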