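---
title: "Detecting goal-directed movements from wrist accelerometry: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting goal-directed movements from wrist accelerometry: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Goal-directed movements (GDMs) — purposeful reaches of the hand toward a
target — are the atomic unit of upper-limb function. After a stroke, their
amplitude and smoothness degrade, and quantifying that degradation outside
the clinic is the core promise of wrist-worn accelerometry. The obstacle is
that a wrist accelerometer records everything: gait-induced arm swing,
fidgeting, and rest look superficially similar to reaching. `gdmwear`
implements a complete analysis chain for this problem:

1. simulate a labelled two-wrist cohort of activities of daily living (ADL),
2. condition the raw signal (band-pass, downsample, integrate to velocity),
3. segment into labelled sliding windows,
4. detect GDM windows with a gradient-boosted classifier under
   leave-one-subject-out (LOSO) evaluation,
5. summarise each subject's inferred GDM periods with a 28-feature
   descriptor, and
6. relate those features to clinical status: stroke-versus-control
   classification and Fugl-Meyer Assessment (FMA) regression with elastic
   nets.

Because the clinical recordings this design targets are proprietary, the
package ships a synthetic cohort generator as a first-class, tested module.
Everything downstream of the generator is agnostic about where the signal
came from.

## The synthetic cohort

`make_cohort()` draws 20 "stroke" subjects and 10 controls by default.
Stroke impairment is Uniform(0.3, 0.9) on a 0–1 scale; controls are 0. The
FMA (upper-extremity motor scale, 0–66 points) is linked to impairment by
`round(61 - 40 * impairment + N(0, 4))`, clipped to [10, 66]. The linear map
was calibrated once, analytically, so that a large stroke group has FMA mean
37 and SD 8.0 — the distribution a stroke cohort of this kind reports — and
is not revisited thereafter. For controls, the non-dominant wrist plays the
role the affected wrist plays in stroke subjects.

`simulate_session()` renders one wrist's raw 100 Hz tri-axial signal from a
task script of four segment types (all boundaries aligned to a 2.5 s
labelling granularity):

* **GDM segments** (bimanual, or unimanual on the active side) are trains of
  minimum-jerk reaches — the standard kinematic model of reaching, position
  $s(\tau) = d\,(10\tau^3 - 15\tau^4 + 6\tau^5)$ — with distance
  0.2–0.6 m and duration 0.5–1.5 s per reach. Impairment degrades them
  three ways: acceleration amplitude is scaled by $(1 - 0.5\,\mathrm{imp})$,
  a 4–6 Hz tremor of amplitude $0.12\,\mathrm{imp}$ m/s² is added, and
  corrective sub-movements (0.5–1.5 cm mini-reaches at a Poisson rate of
  $3\,\mathrm{imp}$ per second) interrupt the smooth profile. The sizes were
  chosen once so that the impaired group shows lower magnitude RMS and
  median and a higher zero-crossing count — the directions the downstream
  group statistics are designed to detect — while keeping the added energy
  small relative to the reaches themselves.
* **Passive segments** are 1.8–2.2 Hz sinusoidal arm swing (gait-like),
  amplitude 1–2 m/s².
* **Task-free segments** are low-amplitude AR(1)-coloured noise
  (RMS 0.08–0.15 m/s²).
* The wrist opposite a unimanual task carries task-free-like signal and is
  *labelled* task-free, matching the labelling convention that the passive
  side of a unimanual activity is not a GDM.

Every segment rides on a 9.81 m/s² gravity vector whose orientation drifts
slowly (periods near one minute, a few degrees), so the preprocessing stage
demonstrably has to remove it. Each subject also receives an
`activity_scale` (Uniform(0.6, 1.5)) multiplying the non-GDM signal only:
people differ in how much incidental movement they produce, independent of
impairment. This term matters for the downstream comparison — without it,
features from entire recordings would be just as clean a group discriminator
as features from GDM periods, which is not how real recordings behave.

The unaffected wrist of a stroke subject retains a mild deficit
(30% of the subject's impairment), reflecting the ipsilesional deficits
commonly observed after stroke.

The default task script is 150 s per wrist with a GDM sample fraction near
0.22 per wrist, in the class-imbalance range such studies report. Script
durations are a free design parameter; this length keeps a full 30-subject
cohort (60 sessions, about 10,000 windows) fast enough to evaluate many
cohorts in one sitting, and nothing in the pipeline depends on it.

**What the generator does not emulate:** sensor noise spectra and
calibration error, orientation-dependent gravity leakage during fast
movement, task-to-task kinematic idiosyncrasy, gyroscope channels, and the
enormous within-subject variability of free-living recordings. Passing the
recovery suites on this generator therefore shows the pipeline is correct
and sensitive under its stated assumptions — not that the published
real-data performance would be reproduced.

## Signal conditioning

The raw signal is band-passed between 0.1 and 12 Hz with a 4th-order
Butterworth filter and downsampled to 25 Hz; velocity is estimated by
cumulative trapezoidal integration of the band-passed acceleration followed
by the same band-pass (which removes integration drift).

Numerical choices:

* **Zero-phase filtering.** The filter is applied forward and backward, so
  the effective amplitude response is the squared single-pass curve and no
  phase distortion shifts the signal against its labels. The acceptance
  checks therefore test the squared response: 1 Hz within 5% of unity,
  20 Hz below 0.1.
* **Cascade instead of a direct band-pass.** The 0.1 Hz edge puts poles at
  modulus ~0.998; the band-pass is realised as a high-pass/low-pass cascade
  whose (b, a) polynomials are better conditioned.
* **Edge handling.** A forward-backward pass with zero initial conditions
  leaves a multi-second transient from the near-DC poles. Each channel is
  linearly detrended (exact for the constant gravity component), extended by
  10 s odd reflection about both endpoints, filtered, and cropped. Measured
  DC rejection exceeds 250 dB; the first and last 2 s of any filtered
  stream are still excluded from property checks.
* **Downsampling** is plain decimation (every 4th sample) after the 12 Hz
  low-pass, which already sits below the 12.5 Hz target Nyquist.
* **Velocity units** are physical m/s from trapezoidal integration. The
  magnitudes of published velocity-feature tables in this area are not
  reproducible without knowing the original integration scaling, so no
  attempt is made to match them; only dimensionless effect sizes are
  compared.

## Windowing and labels

A sliding window of 3 s with 70% overlap is applied per wrist: 75 samples at
25 Hz with hop `floor(75 * 0.3) = 22` (the fractional hop is floored; denser
windows lose no data). A window is a GDM window when **at least one third**
of its samples are GDM — "one third" is read inclusively, so 25 of 75
qualifies. A fractional `win_s * fs` is floored to whole samples so that the
window length follows the configuration rather than a hard-coded 75. The six
channels are acceleration x, y, z and velocity x, y, z. Per-channel
normalization statistics (mean, SD pooled over all samples of all training
windows) are estimated on each split's training subjects only.

## The 28-feature descriptor

For each signal (acceleration, velocity), 14 statistics: three axis-pair
Pearson correlations; the number, mean length, and length entropy of
zero-crossing runs (pooled over the three axes); and eight statistics of the
per-sample magnitude — min, max, median, RMS, dominant frequency over
energy (periodogram peak frequency in Hz divided by the total non-DC
periodogram sum), skewness, excess kurtosis, and entropy.

Conventions the package fixes where the field leaves them open:

* zero samples adopt the neighbouring nonzero sign, so sign runs are
  well-defined; an all-zero axis is one full-length run;
* crossing-run statistics are pooled across axes rather than averaged
  per-axis;
* crossing-length entropy uses the exact discrete run-length distribution
  (natural log); magnitude entropy uses a 100-bin histogram over the
  epoch's own range (base 2, so the ceiling is log2(100) ≈ 6.64 — consistent
  with published acceleration-entropy values just under that ceiling);
* the periodogram is a plain FFT periodogram with the DC bin excluded from
  the peak search and no Welch averaging (epochs are short);
* kurtosis is excess kurtosis (published tables show negative values, which
  raw kurtosis cannot produce);
* zero-variance input yields skewness, kurtosis and entropy of 0.

These are documented package conventions, not claims about unpublished
reference code; consequently numeric equality with published per-feature
means is out of scope, while effect sizes recomputed from published
summaries are tested exactly.

## Detection and evaluation

The detector backend is gradient-boosted trees (`xgboost`, single-threaded
for determinism) on the 28-feature descriptor of each normalized window —
the representation a tree ensemble handles well, as opposed to raw
75 × 6 matrices. Class imbalance is handled by weighting each class with the
other class's proportion. Training early-stops on validation AUC; the
operating threshold maximizes the geometric mean of sensitivity and
specificity over the midpoints of sorted unique validation scores (the exact
optimum for a step-wise ROC), ties broken toward the lower threshold. A
convolutional backend was considered and deliberately left out: the
reference implementation of that family depends on training details and
data unavailable here, and the tree backend is the deterministic baseline
the evaluation needs.

Evaluation is leave-one-subject-out: each subject is the test set once;
`ceiling(0.1 ×` remaining`)` subjects are the validation set, drawn by a
seeded RNG subject-wise (never window-wise, to respect subject
independence); normalizer, class weights, model, and threshold are all
refitted within each split. AUC is the tie-aware rank statistic. Split
metrics are aggregated by unweighted mean. A test subject with one class
yields threshold-based metrics and an `NA` AUC with a warning.

## Downstream analyses

Window predictions are folded back to samples by majority vote over the
windows covering each sample (ties to non-GDM; an "any covering window"
rule is available as a configuration flag). In `run_pipeline()`, each
subject's mask comes from the LOSO fold in which that subject was the test
subject, so downstream inputs are held-out predictions. Each subject's
masked samples from both wrists are concatenated and the 28 features
computed once per subject (subjects with fewer than 8 masked samples are
excluded with a warning); the same is done without a mask for the
entire-recording comparison.

Stroke-versus-control classification and FMA regression use
elastic-net-penalized models under subject-level LOSO: for each held-out
subject, the mixing parameter is chosen from {0.1, 0.5, 0.9} and the penalty
strength by seeded inner cross-validation (stratified for classification) on
the remaining subjects, with features standardized inside each fold by the
fitting routine. When a group is too small for nested cross-validation
(fewer than 3 per class after holdout), the penalty is chosen on the
alpha = 0.5 path by a BIC-style criterion instead. Explained variance is
`1 - Var(residual)/Var(FMA)`, floored at −1. Group statistics use Cohen's d
with the pooled SD and the matching pooled-variance two-sided t-test (sign
convention stroke − control); this convention reproduces published effect
sizes from published summary tables with n = (20, 10), which is how the
worked-example tests validate it.

One asymmetry worth knowing: the full pipeline derives masks from LOSO
held-out predictions, while the multi-seed downstream recovery suite trains
a single pooled detector per cohort (subject-wise 80/20 split) and predicts
all windows. The suite compares *feature sources*, not detector
generalisation, and the pooled detector keeps ten cohort evaluations cheap.

## Problem sizes and determinism

Default evaluations in the tests and the acceptance script use 30-subject
cohorts (60 sessions of 150 s, ≈10,000 windows), three cohort seeds for
detection recovery, ten reduced cohorts for the impairment-monotonicity
property, and five cohorts for the downstream source comparison — sizes
chosen so a complete run stays in the minutes range on one CPU while leaving
the Monte-Carlo directions stable. Every stochastic step (cohort draws,
session rendering, validation splits, inner CV folds, gbt training) is
seeded from a single master seed, and identical configurations rerun to
byte-identical JSON reports.

## Known limitations

* The simulator's impairment effects are stylised; effect sizes it produces
  are larger than clinical tables report, so recovery thresholds are
  directional, not magnitude-matched.
* The crossing-length *entropy* contrast is not calibrated in the
  generator; its sign may differ from published tables even while all
  calibrated contrasts match.
* Velocity feature magnitudes depend on integration scaling (see above).
* Windows shorter than the configured length at the end of a session are
  dropped, as in any fixed-hop scheme.
* The detector's near-ceiling synthetic performance reflects the
  separability of the simulated classes, not expected real-data AUC.
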