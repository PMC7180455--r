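---
title: "Two-stage Mahalanobis cleansing of accelerometer activity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage Mahalanobis cleansing of accelerometer activity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable human-activity-recognition (HAR) pipelines train classifiers on
features extracted from short windows of wrist-accelerometer signal.  Real
recordings contain *attribute noise*: windows where the sensor slipped, the
subject fumbled, or the signal was otherwise corrupted, while the activity
label stayed the same.  Such windows are multivariate outliers in feature
space.  They are harmless to look at, but they distort the neighbourhood
structure that proximity classifiers such as k-nearest-neighbours rely on,
and so degrade accuracy precisely in the realistic setting where the model is
applied to raw, uncleaned data.

`mdcleanse` implements a two-stage multivariate screen for such windows and
the complete evaluation harness needed to measure its effect on classifiers.

## The method

Each recording (one subject performing one activity, nominally 2 min at
51.2 Hz) is cut into non-overlapping 4 s windows and summarized by 51 time-
and energy-domain features.  For a group of windows, collect the screening
variables into an $n \times p$ matrix $X$ (by default $p = 3$: the windowed
mean accelerations $\bar a_x, \bar a_y, \bar a_z$), estimate the mean vector
$\mu$ and sample covariance $V$ (divisor $n-1$), and compute for every window

$$ M_i = \left[ (X_i - \mu)^\top V^{-1} (X_i - \mu) \right]^{1/2}. $$

Under approximate multivariate normality $M_i^2$ follows a $\chi^2_p$ law,
so a window is flagged as an outlier when $M_i^2$ exceeds the $(1-\alpha)$
quantile of $\chi^2_p$.  Screening is applied twice:

1. **Stage 1 — within recording.**  Each subject-by-activity window table is
   screened independently at $\alpha_1$.  This removes windows that are
   atypical *for that person doing that activity*.
2. **Stage 2 — within activity.**  Stage-1 survivors are pooled per
   activity and screened again at $\alpha_2$, with $\mu$ and $V$ refitted on
   the pooled table.  This removes windows atypical for the activity as a
   whole.

The four level combinations $\alpha \in \{0.05, 0.01\}^2$ are written
`95_95`, `95_99`, `99_95`, `99_99` (confidence levels per stage).  Both
stages are single-pass: the model is not refitted after removal, so the
well-known masking and swamping failure modes of non-robust Mahalanobis
screening are acknowledged rather than mitigated — robust estimators (MCD,
M-/S-estimators) are deliberately out of scope.

Numerical choices: distances are computed by a linear solve, never an
explicit inverse; a numerically singular $V$ receives a ridge
$10^{-8}\,\mathrm{tr}(V)/p$ with a warning (identical rows then all sit at
distance zero and nothing is flagged); groups smaller than $p + 2$ rows pass
through unflagged with a warning so one short file cannot abort a
hundreds-of-files run; the flag compares $M_i^2$ with the $\chi^2$ quantile
directly, avoiding a redundant square root.  The $\chi^2$ threshold is used
exactly as stated even though the finite-sample law of an estimated-parameter
$M_i^2$ is a scaled Beta; with the ~20-30 windows per recording this
approximation is tolerable and it is what the method prescribes.

## The 51 window features

`feature_catalog()` lists all 51 features: per-axis and signal-magnitude-
vector (SMV) means, minima, maxima, ranges, standard deviations (divisor
$n-1$), RMS values, trapezoidal integrals ($dt = 1/\text{rate}$), the signal
magnitude area (SMA), mean log / exp / exp-squared transforms, mean squared
accelerations, spectral entropies, and per-axis medians.  Three conventions
deserve notice:

* **Mean logarithm** is computed as $\overline{\log(|v| + 10^{-9})}$, since
  axis accelerations oscillate around zero where a bare logarithm is
  undefined.  The offset is configurable (`eps_log`).
* **Exponential features** clip their exponent argument at 50 before
  exponentiation, so a single extreme sample cannot overflow the feature to
  infinity while typical values are untouched (`exp_cap`).
* **Spectral entropy** is the Shannon entropy (natural log) of the
  DC-removed one-sided power spectrum normalized to sum to one; a constant
  window returns 0 by convention, a bin-aligned pure tone returns 0, and
  white noise approaches $\log\lfloor L/2\rfloor$.  "Entropy of the FFT" is
  ambiguous; this is the standard structural-feature reading, and the choice
  is isolated behind `spectral_entropy()`.

The schema intentionally contains the mean of squared values twice
(`meansq_*` and `sqmean_*`): the source feature list enumerates the quantity
in two separate slots, and the 51-column schema is treated as authoritative.
Feature extraction is pure arithmetic per window, so cross-feature
identities (range = max − min, RMS² = mean square, the $n-1$ variance
identity) hold to machine precision and are asserted in the tests.

## Feature selection and classifiers

Feature subsets are chosen by correlation-based feature selection (CFS):
the merit of a subset of $k$ features is
$k\,\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$, where $\bar r_{cf}$ and
$\bar r_{ff}$ are mean feature-class and feature-feature symmetrical
uncertainties after equal-width 10-bin discretization.  The search is
forward best-first with a stagnation limit of five non-improving
expansions and schema-order tie-breaks, mirroring the common Weka
configuration ("BestFirst, direction forward, searchTermination 5") that
the evaluated protocol names only by its flag string; this reading is an
interpretation, stated here once.  On small feature sets the search is
verified against exhaustive enumeration.

Two classifiers are evaluated, matching the protocol's final pair:

* **KNN**, $k = 1$, Euclidean distance on features standardized to
  train-set mean and SD.  Standardization is an implementation choice the
  protocol leaves unstated: the 51 features mix units and magnitudes
  (medians near 10 m/s², exponentials near $10^{20}$), and unscaled
  Euclidean KNN would be degenerate.  It is applied identically in every
  condition, so comparisons remain fair.
* **Random forest**, 100 trees, $\lfloor\sqrt{p}\rfloor$ candidate split
  variables, seeded for reproducibility.

## The experiment protocol

`run_experiment()` repeats, ten times by default: split every recording's
windows 66/34 into set 1 (development) and set 2 (raw held-out); for each
condition (`raw` plus the four cleansing levels) cleanse set 1, select
features on cleansed set 1, train both classifiers; evaluate by 10-fold
stratified cross-validation within set 1, against set 2 cleansed at the
matched level, and against untouched raw set 2.  Ten repetitions × five
conditions × two classifiers instantiate exactly 100 models.  Set 2 never
participates in cleansing decisions, selection, or training, so the
raw-unseen estimate is leak-free (asserted in tests).  Feature selection is
deliberately performed once per condition on the full set 1 — the evaluated
protocol's placement, which its own discussion notes is optimistic;
`cross_validate(selector = ...)` provides the fold-internal variant.

The statistical layer mirrors the protocol's analysis: per-model mean and
SD of the F-measures over repetitions, Anderson-Darling composite-normality
p-values, pairwise Welch t-tests (pooled available via `pooled = TRUE`),
and one-way ANOVA across the four cleaned levels, all at a configurable
$\alpha$ defaulting to 0.01.  No multiple-testing correction is applied, to
mirror the analysis being reproduced; treat the pairwise tables
accordingly.  `f_t_test()` exposes one-sided alternatives for directional
hypotheses such as "cleansing improves KNN".

## The synthetic-data generator

The study dataset (423 files, 18 activities) is not public, so the package
ships a generator whose defaults define the conditions under which the
method is demonstrated: six activities × five subjects, 120 s at 51.2 Hz,
and segment-level contamination at rate 0.1 with a 6-noise-SD mean shift.

Each activity is: a constant per-axis offset (the gravity projection seen
at the wrist), weak per-axis sinusoids (quasi-periodic movement), Gaussian
noise with a prescribed 3×3 axis correlation (imposed via the symmetric
square root of the correlation matrix), and a slow Ornstein-Uhlenbeck
baseline drift shared by all three axes' innovations (stationary SD 0.8-1.0
m/s², correlation time 3 s in the default library).  The drift is the
deliberate non-stationarity of the model: real wrist recordings wander
(posture shifts, movement variability), and without it every window of a
recording is a near-replica of every other, making classification
unrealistically easy and outlier screening trivially sharp.

Contamination operates on whole window-length segments so that injected
outliers correspond one-to-one to analysis windows.  A corrupted segment's
noise SD is inflated (factor 2 by default) and its signal is displaced by a
shift with the Euclidean magnitude of `mean_shift * noise_sd` but a
direction drawn uniformly at random per segment.  The random direction is
essential to what "attribute noise" means here: corrupted windows scatter
rather than forming a stable displaced cluster, so they cannot be learned
as a legitimate sub-class — a fixed-direction shift would be a systematic
sensor bias, which is a different phenomenon and one that cleansing should
*not* be expected to help with.  An optional ramped low-variance "learning
curve" can be prepended/appended to emulate subjects settling into the
activity; `trim_recording()` is its counterpart on the analysis side.

The default activity library distinguishes activities mainly by offset
(posture) with weak, partially overlapping rhythmic components.  Parameters
were fixed once, during generator design, so that classes are separable but
not trivially so, corrupted segments are unambiguous outliers to the
three-mean screen, yet land often enough inside foreign class regions to
distort nearest-neighbour structure — the regime the cleansing method is
intended for.  They are configuration, not measurements.

What the generator does **not** emulate: biomechanically realistic
waveforms, device-specific calibration, label noise, heteroscedastic or
impulsive sensor error, missing samples, and between-subject variation in
activity style (all subjects share one spec per activity; subject identity
enters only through independent noise/drift realizations).  Consequently,
passing tests demonstrate the method's behaviour under its own assumptions
(elliptically distributed clean windows plus scattered gross outliers), not
performance on any real dataset.

Determinism: one master seed derives a per-recording seed from the activity
and subject indices, so datasets are reproducible file-by-file and
independent of generation order.  The guarantee that clean window means
stay within $5\sigma/\sqrt{L}$ of the offset applies to the stationary
part of the model (drift disabled); with drift on, window means wander by
design.

## Problem sizes and runtime

The test-suite and acceptance-script sizes are the package's documented
study scale: 30 recordings (six activities × five subjects) of 120 s, about
900 windows, ten split repetitions, 100 trained models; Monte-Carlo
calibration checks use 20 000 observations and 10 000 null replicates.  A
full suite run takes on the order of a minute on a single CPU.

## Known limitations

* Single-pass, non-robust screening inherits masking/swamping at high
  contamination rates; the defaults (10%) are well inside its working range.
* The $\chi^2$ cutoff ignores the estimated-parameter correction, slightly
  mis-calibrating flag rates for very short recordings.
* CFS-once-per-condition leaks selection information into the
  cross-validated F (not into the raw-unseen F); this mirrors the evaluated
  protocol and is flagged where it applies.
* The Anderson-Darling p-value requires at least eight observations; with
  five to seven the summary reports `NA` rather than a value.
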