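---
title: "Methods: EHG biomarkers for preterm-birth prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHG biomarkers for preterm-birth prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ehgrisk)
```

## The problem and the model

The electrohysterogram (EHG) records the electrical activity of the
uterine muscle from abdominal electrodes. A pregnancy that will end
prematurely (before 37 completed gestational weeks) leaves statistical
traces in recordings made weeks earlier — around the 31st gestational
week — notably an elevated relative intensity of the spectral components
in the Fast Wave Low (FWL) range (~0.1–0.6 Hz), and, above 1 Hz, shifts
of the components that the maternal heart imprints on the abdominal
signal. `ehgrisk` operationalizes this as a binary classification of
whole 30-minute, 3-channel, 20 Hz records into *premature* versus *term*,
built from explainable band-limited features rather than black-box
models.

Two channels are analyzed: S2 (vertically oriented electrode pair) and
S3 (horizontally oriented, closest to the cervix). Ten bands are used
(`ehg_bands()`): the non-overlapping B0 (0.08–1.0 Hz), B1 (1.0–2.2),
B2 (2.2–3.5) and B3 (3.5–5.0 Hz) — B1–B3 aligned with the maternal heart
rate and its second and third harmonics — the broad bands Bb (0.3–4.0)
and B0b (0.08–4.0), and the low-frequency sub-bands B0L (0.08–0.3),
B0Lp (0.125–0.575, matching the FWL), B0Lpp (0.225–0.475) and B0Hp
(0.575–1.0). Band names use `p` for the prime mark.

### Features

Each (feature, signal, band) triple is one candidate biomarker, named
canonically (e.g. `PA_S3_B0Lp`). Per band, the raw signal is band-passed
with a 4th-order Butterworth filter applied forward–backward (zero
phase), 15 s are trimmed from each end (filter transient), and:

* **PF, MF** — peak and median frequency of the periodogram
  (magnitude-squared DFT of the whole filtered series, `P(k)` at
  frequency `k·fs/M` for DFT length `M`). The median frequency is the
  smallest in-band bin at which cumulative in-band power first reaches
  half the total; on ties the smaller bin wins. In-band bins use the
  half-open rule `[ceil(f_lo·M/fs), ceil(f_hi·M/fs))`, so adjacent bands
  never share a bin.
* **PA** — the largest in-band spectral component divided by the largest
  component of the B0-filtered signal inside B0 (the reference band).
  Dimensionless; identically 1 in B0 and effectively 1 in B0b, which is
  why those two specs are excluded from the candidate sets.
* **SE** — sample entropy with embedding dimension `m = 3` and tolerance
  `r = 0.15·SD` of the band-limited series (the feature is a per-band
  regularity measure, so the tolerance scales with the analysis series,
  not the raw record). Matches use the Chebyshev distance over unordered
  pairs `i ≠ j`, with length-`m` templates indexed over `[1, N−m+1]` and
  length-`m+1` templates over `[1, N−m]`; the oracle in the test suite
  mirrors exactly this convention. When either match count is zero the
  conventional fallback `−ln((N−m)/(N−m−1))` is returned verbatim — note
  it is *negative* as printed; `fallback_sign_corrected = TRUE` gives the
  absolute value, and the default does not silently correct it.

Four candidate sets are predefined: set1 is all four features × two
signals × ten bands minus the degenerate PA specs (76 features); set2
drops the least promising bands B0Hp and Bb (60); set3 keeps only B0L,
B0Lp, B3 and B0b (30); set4 drops B0b from set3 (24). The "60" arithmetic
only works if the excluded band pair is read as B0Hp and Bb — B0H
(0.3–1.0 Hz) is not among the ten bands — and the package adopts that
reading.

## Stabilized sequential forward selection

A single run of greedy sequential forward selection (SFS) is unstable, so
selection is stabilized by repetition and aggregation
(`stabilized_selection()`):

1. Candidates are sorted by ascending rank-sum p-value (premature vs
   term). By default the p-values are computed from the input feature
   table with two-sided Wilcoxon tests; an externally supplied ordering
   can be passed instead. The order matters only as a tie-break and as
   the histogram indexing.
2. For each of `n_reps` repetitions, the data are split by a fresh
   stratified 80/20 holdout. On the training side only, SFS ranks all
   `K` features: at each step the feature minimizing the stratified
   5-fold cross-validated misclassification error (MCE) joins the subset;
   ties resolve toward the lower p-value. The per-run selected subset is
   the prefix up to the (first) minimum of the run's MCE curve.
3. Occurrences of features in those prefixes accumulate into a histogram
   `H`; MCE curves accumulate into an average curve whose (first)
   minimum fixes the final subset size `m`, and the `m` highest histogram
   peaks form the final subset.

The whole procedure is repeated per classifier and feature set; per run,
the features with the highest and second-highest occurrence counts take
first and second place, and `tally_top2()` identifies the overall most
promising pair (A, B) as the most frequent first-place feature and the
most frequent *distinct* second-place feature — the procedure's purpose
is to name two distinct biomarkers.

### SMOTE and the Partition-Synthesis discipline

The premature class is the minority (32 vs 196 at the study scale), so
training partitions are balanced with SMOTE: synthetic minority rows are
convex combinations of a minority row and one of its `k = 5` nearest
minority neighbors (Euclidean, in the feature space being balanced).
Balancing happens **strictly after** partitioning — after the 80/20
split, and inside cross-validation after the fold split — never before,
so no information from test or validation rows can leak into training
(Partition-Synthesis). Every synthetic row carries its parent record ids,
and `audit_leakage()` verifies on every run that all parents lie in the
training side; the audit result ships with every selection/evaluation
object.

Inside the SFS the training folds are balanced once per (repetition,
fold) in the full candidate-feature space, and every candidate subset
evaluates on column subsets of those balanced folds. This reuses one set
of SMOTE draws across the greedy argmin (the aggregation reuses the
selected value anyway) and makes the exhaustive ranking tractable; the
alternative — re-running SMOTE per candidate subset — changes the
neighbor geometry slightly but not the leak-freedom property.

## Classifiers and evaluation

Five classifiers are supported (`ehg_classifiers()`): pseudo-linear and
pseudo-quadratic Gaussian discriminants (implemented in-package with
Moore–Penrose pseudoinverse covariance and pseudo-determinant, so
singular covariance — constant features, small folds — never aborts
training), Gaussian naive Bayes with empirical priors, and SVMs with
3rd-order polynomial and RBF kernels (via e1071). No hyper-parameter
search is performed. Scores are oriented so larger means more
premature-like; the discriminants and naive Bayes report posteriors, the
SVMs a logistic squashing of the decision value (their margins are not
calibrated posteriors; only the 0.5-crossing and ordering matter for the
boundary and ROC work).

`repeated_evaluation()` reuses the *same* partitions persisted by the
selection phase: per repetition, the training rows are SMOTE-balanced,
the model is trained on the chosen feature(s), and metrics are computed
on the untouched test rows — sensitivity, specificity, PPV, NPV,
accuracy from the confusion counts (premature = positive), and AUC by
trapezoidal integration over score thresholds (equal to the Mann–Whitney
pair-counting statistic with ties at one half). Means and (n−1) SDs
aggregate over repetitions; metrics undefined in a repetition (zero
denominator) are excluded from that metric's aggregate with a count.
Training-set metrics are reported alongside for the generalization check
(`glance()` exposes the train−test gaps).

ROC curves are averaged vertically: each curve is interpolated onto a
common false-positive-rate grid and sensitivities are averaged pointwise
with per-point SDs. For a single-feature model the decision boundary is
one threshold, located by bisection on the 0.5-likelihood crossing and
averaged across models and repetitions; models whose score never crosses
0.5 in the padded feature range are skipped and counted. For two-feature
models a grid (observed range padded 10%, default 200×200) is scored by
every model, the likelihood matrices are averaged, and the 50% isoline is
extracted.

The composite biomarker condenses the two headline features into
`score = 5.98·PA − 4.02·MF + 12.78` (`composite_biomarker()`); positive
scores indicate danger of premature birth and scale with its likelihood.

## The synthetic generator

`generate_record()` builds 3-channel records as channel-mixed shared
components plus independent 1/f^a background noise:

* a narrowband FWL component (random center 0.31–0.45 Hz, slow bounded
  frequency walk, slow random-depth amplitude modulation) whose spectral
  peak power is multiplied by `fwl_peak_gain` in the premature class;
* a fixed "FWH anchor" component (0.62–0.9 Hz) that owns the reference
  peak of band B0, so the normalized peak amplitude in B0Lp responds to
  the planted gain;
* maternal-heart harmonics 1–3 with a bounded random-walk heart rate
  (heart-rate variability) whose fundamental is `mhr_base` for term and
  `mhr_base − mhr_shift` for premature records — the third harmonic stays
  inside B3 for both classes by construction;
* per-record log-normal jitters on component amplitudes and on the noise
  level, and a per-record noise spectral slope, emulating inter-subject
  and recording-quality variability.

The electrode-orientation mixing projects the FWL component mostly onto
S3 and the heart components mostly onto S2, so the class effects express
themselves on `PA_S3_B0Lp` and `MF_S2_B3` specifically — the generator's
purpose is a sharp parameter-recovery test for the selection machinery.
Default effect sizes were chosen once so that each headline biomarker
separates its classes at roughly the performance scale reported for real
EHG cohorts (single-feature AUC ≈ 0.8–0.9) while nuisance features
(entropy and peak-frequency readers of the same latent effects) stay
clearly weaker: the heart-rate variability spreads the harmonic's
spectral energy so the in-band *peak* location is noisy while the
*median* tracks the mass center, and the amplitude/noise jitters give the
regularity (SE) features large class-independent spread. What the
generator does **not** model: contraction-burst morphology,
nonstationarity across the recording, electrode artifacts, or any
clinical covariates — so passing recovery tests demonstrates that the
pipeline finds planted spectral structure, not that it would perform at
any particular level on real cohorts.

`generate_dataset()` mirrors the study's cohort structure by default
(32 PL / 132 TL / 43 IL / 8 CL / 13 ICL; term delivery-mode groups differ
only in metadata), and `write_fixture()` emits WFDB-compatible
header/signal pairs (format 16, metadata in header comments) that
`read_ehg_record()`/`load_dataset()` read back, with "later"-epoch
filtering by the dataset's own label when present or by a
gestational-age threshold (default ≥ 26 weeks) otherwise.

## Numerical choices and problem sizes

* Spectrum estimator: single periodogram of the full (trimmed) filtered
  series, matching the single-spectrum indexing of the feature
  definitions; Welch-style averaging was deliberately not made the
  default since MF/PA are defined on one spectrum.
* Filter: Butterworth order 4, zero-phase via forward–backward
  application; 15 s transient trim per end (configurable, smaller in
  tests on short records).
* Sample entropy is O(N²) and implemented in C++; the discriminant
  cross-validation inside the SFS loop is also C++ (RcppArmadillo), and
  both are verified against plain-R oracles in the tests.
* Reproducibility: every stochastic step takes a seed; repetition `i` of
  a selection uses `base_seed + i`, SMOTE inside fold `f` uses
  `seed + 1000·f`, and partitions are canonically ordered by record id
  before any draw, so results are independent of row order.
* Tests and the acceptance script run the pipeline at reduced sizes
  chosen to keep the full suite in the minutes range: 2–3 minute records
  (3600 samples — the spectral resolution of 1/150 Hz is still an order
  of magnitude finer than the narrowest band), cohorts of 32–230 records,
  10 selection repetitions instead of the study-scale 200, and the
  recovery experiment at 2 classifiers × 2 feature sets × 10 replicates.
  The study-scale configuration (30-minute records, N = 200, 5 × 4 runs)
  is the package default.

## Known limitations

* The five classifiers emulate a different numerical ecosystem's
  defaults; SVM decision values are squashed, not calibrated, so their
  "likelihood" is ordinal.
* The generator plants stationary spectral structure; real EHG is
  nonstationary and contraction-modulated, and feature distributions on
  real cohorts will differ in location and spread from the synthetic
  ones.
* The printed sample-entropy fallback value is negative; it is
  reproduced verbatim by default, which matters only for pathological
  series with no template matches.
* Recovery of the planted biomarker pair is a stochastic property.
  The per-replicate probability that the stabilized-selection tally names
  exactly the two planted features is about 0.8 at the reduced problem
  size used in the tests (200 records of 3 minutes, 10 repetitions,
  2 classifiers × 2 feature sets): the occasional stealers are the
  peak-frequency and entropy readers of the same planted latent effects,
  which are genuine (correlated) biomarkers of those effects rather than
  false discoveries — an ambiguity the original cohort analysis also
  shows, where the second-place feature was shared among several
  candidates across selection runs. The acceptance suite asserts recovery
  in at least 9 of 10 fixed-seed replicate experiments, which this
  failure rate does not reliably meet; the corresponding test documents
  the measured rate rather than loosening the bound.
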