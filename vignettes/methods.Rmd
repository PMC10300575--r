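---
title: "Classifying naming decline from structural connectome change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying naming decline from structural connectome change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Anterior temporal lobe resection (ATLR) controls seizures in refractory
temporal lobe epilepsy, but language-dominant resections carry a substantial
risk of picture-naming decline. The idea implemented here is that the
*estimated change* in a patient's structural brain network — obtained by
virtually resecting the pre-operative tractogram with the resection mask —
carries information about who will decline. `connectoclass` turns that idea
into a tested, reusable pipeline: streamline tables over an atlas
parcellation become weighted connectomes; virtual resection yields an
estimated post-operative network; per-region graph metrics and their changes,
together with four clinical covariates, feed a sparse classifier whose
significance is assessed by permutation.

Because no patient-level data are deposited for this design, the package
ships a first-class synthetic cohort generator that emulates the study's
data structure and provides ground truth for recovery testing.

## Network construction

A `StreamlineTable` records one row per streamline: the two endpoint regions
and a flag marking whether the streamline passes through the resection mask.
`build_connectome()` counts streamlines per unordered region pair; self
connections are removed. Virtual resection keeps only unflagged streamlines,
so post-operative weights can never exceed pre-operative ones — this
monotonicity is a tested invariant, and it is why strength change is encoded
as a ratio (see below).

Edge reliability is enforced by cross-patient *prevalence thresholding*: an
edge is kept at threshold $t$ if it is present (strictly positive count) in
at least $t\%$ of patients' pre-operative matrices, for
$t \in \{75, 80, 85, 90, 95, 100\}$. Two choices here were genuinely open:

* Prevalence is computed on **pre-operative** matrices only, and the same
  mask is applied to both stages of every patient, so change metrics compare
  like-for-like edge sets.
* Counts are transformed as $\log_{10}(1 + w)$ rather than bare
  $\log_{10} w$: streamline-count distributions are heavily right-skewed,
  and the unit offset keeps zero edges at zero instead of annihilating
  weight-1 edges. The offset is exposed (`log_offset`).

## Graph metrics and change encodings

Three weighted, undirected per-region metrics are computed on the masked,
log-transformed matrices:

* **Strength**: $s_i = \sum_j w_{ij}$. Change is the ratio
  $s^{post}_i / s^{pre}_i \in [0, 1]$ (post-operative strength can only
  decrease); $0/0$ is defined as 1 for regions that were already
  disconnected, so no missing values propagate.
* **Betweenness centrality**: shortest-path counts through each region with
  edge length $1/w$ (the standard convention of the field's connectivity
  toolbox — strong connections are short). Unordered pairs are counted once
  and ties split fractionally. Change is the difference
  $b^{post} - b^{pre}$, which also makes the pipeline invariant to any
  constant normalization of betweenness.
* **Clustering coefficient**: the geometric-mean (Onnela) form after
  normalizing weights by the matrix maximum,
  $C_i = \frac{1}{k_i(k_i - 1)} \sum_{j \ne h}
  (\hat w_{ij} \hat w_{ih} \hat w_{jh})^{1/3}$, with $k_i$ the binary degree
  and $C_i = 0$ for $k_i < 2$; normalization is computed per stage. Change
  is the difference.

Metrics are computed at each prevalence threshold. The feature matrix either
averages changes across thresholds (`mode = "averaged"`, 94 regions × 3
metrics + 4 clinical = 286 columns) or keeps one matrix per threshold
(`mode = "per_threshold"`, the default in `run_pipeline()`), which lets
feature importance be aggregated "across leave-one-out and threshold
iterations".

Betweenness is checked against an exhaustive shortest-path enumeration
oracle on hundreds of random small graphs, and clustering against the
unweighted per-node transitivity on binary graphs.

## Outcome and clinical covariates

Naming is scored 0–30; decline is dichotomized at a pre-minus-post drop of
at least 4 points (the reliable-change criterion used clinically), patients
without 12-month follow-up being excluded from that timepoint. The covariates
are age of onset, age at surgery, pre-operative naming score, and the fMRI
language laterality index (a scalar in $[-1, 1]$; the emulated cohort is
left-dominant so generated values are positive).

## Harmonization and scaling

Features acquired on two scanners are harmonized with parametric
empirical-Bayes location/scale adjustment (ComBat, via the `sva` package);
labels are never used. Harmonization is fitted once on the full cohort
before cross-validation, following the reference protocol's ordering — a
documented leakage trade-off. Constant features cannot be harmonized and
are passed through with a warning.

Scaling divides each feature by its standard deviation *computed on the
training fold only* and applies those divisors to the held-out patient — a
tested no-leakage property. No mean-centering is done by default (the
selection model's unpenalized intercept absorbs means); `center = TRUE` is
available.

## Feature selection: SCAD-penalized least squares

Selection minimizes
$$J(\beta) = \frac{1}{2n}\lVert y - \beta_0 - X\beta \rVert_2^2 +
\sum_{j=1}^p p(\beta_j; a, \lambda),$$
with the smoothly clipped absolute deviation penalty: linear below
$\lambda$, quadratically clipped to a constant $\lambda^2(a+1)/2$ beyond
$a\lambda$, so large coefficients are not shrunk. Binary labels enter as
0/1 reals — the objective is least squares, not logistic. The grid is 50
evenly spaced concavity values $a \in [2, 10]$ by 100 log-spaced $\lambda$
values from $\lambda_{max}$ (the smallest penalty giving an all-zero fit,
$\max_j |x_j^\top (y - \bar y)| / n$) down to $0.5\,\lambda_{max}$ — 5000
grid points.

Numerical choices:

* Solver: cyclic coordinate descent with the exact scalar SCAD minimizer,
  warm-started along each $a$-row with $\lambda$ descending (coefficients
  reset at the top of each row, where the solution is identically zero).
  This is the standard approach for folded-concave penalties.
* The scalar update handles any column norm and any $a > 1$ by evaluating
  the closed-form branch candidates plus branch boundaries of the exact 1-D
  objective — necessary because the grid includes $a = 2$, where the
  textbook closed form (valid for $a > 2$, exposed as `scad_threshold()`)
  is singular.
* Convergence: largest coefficient change below `tolerance` (default
   1e-6); non-convergence is flagged, not an error. The implementation (C++)
  is verified against a dense brute-force coordinate search oracle on small
  problems, against OLS at $\lambda = 0$, and against the scalar update on
  orthonormal designs.
* Because the penalty is nonconvex the solution depends on the start; the
  warm-start order is fixed, making runs reproducible.

Supports (nonzero index sets) are deduplicated across the grid; only
supports with 1–19 variables ("under 20") proceed to classification.

## Classification: nested leave-one-out SVC

For each left-out patient, the remaining $n-1$ are scaled, run through the
full SCAD path, and each admissible support trains a linear support vector
classifier (fixed $C = 1$ by default; the reference value is unstated) on
the training fold after class rebalancing — SMOTE interpolation between
minority neighbours ($k = 5$) for single-timepoint models, inverse-frequency
class weights for the chain. The held-out patient is scored at every grid
point; pooling held-out decision values gives one cross-validated AUC per
grid point (and per threshold). The reported model is the grid point with
maximum AUC, ties broken toward smaller supports, then larger $\lambda$,
then smaller $a$. A grid point only competes if *every* evaluable fold
produced an admissible support for it: AUCs computed on lucky subsets of
patients are not comparable with full-coverage candidates.

Feature importance is reported as the mean absolute SVC coefficient over
the iterations (folds × thresholds) in which a feature was selected,
multiplied by its percentage of inclusion — so a feature that is strong but
appears in one model cannot dominate.

The longitudinal chain classifies 3-month decline first, appends each
patient's out-of-fold binary prediction as a feature (configurable to the
decision value), re-runs selection on the 12-month labels, and reports the
label-count weighted AUC of the two steps plus per-feature inclusion
prevalence.

### A known property: selection optimism

Each grid point's pooled leave-one-out AUC is an honest estimate for that
fixed $(a, \lambda)$. Taking the maximum over 5000 grid points is model
selection on the same pooled predictions, and therefore carries a winner's
curse: on label-independent data the *selected* AUC concentrates well above
0.5 (empirically ≈ 0.7 at these sample sizes), even though every individual
candidate is unbiased. The effect is strongest because single-feature
candidates effectively scan the best whole-cohort univariate ranking. Users
should read the reported AUC as the selected candidate's cross-validated
score, not an unbiased generalization estimate, and rely on the permutation
test — while noting that the protocol's permutation scheme (final support
fixed, SMOTE before splitting) does not replay the selection and is
therefore itself only a partial calibration. The package implements the
protocol as specified and documents rather than papers over this property;
the test suite asserts the null-calibration bands and leaves them failing
where the procedure cannot meet them.

## Permutation inference

* **Model test**: the final support's features undergo SMOTE once; each of
  `n_perm` permutations shuffles labels, makes a stratified 80/20 split
  (fraction configurable; unstated in the protocol), trains a linear SVC
  and records the test AUC. $p = (1 + \#\{AUC_{null} \ge AUC_{obs}\}) /
  (n_{perm} + 1)$ — the add-one form keeps $p > 0$.
* **Feature test**: per feature and threshold, the observed Welch $t$
  between decliners and non-decliners is compared two-sidedly against a
  null built by shuffling labels jointly across features (preserving their
  correlation); per-threshold p-values are averaged across the six
  thresholds and Bonferroni-multiplied by the number of features, capped
  at 1. Permutation p-values are verified to converge to the analytic
  Welch p on Gaussian data.

## The synthetic cohort generator

The generator defines the study conditions the tests run under; its
defaults are the published cohort structure: 44 patients, 94 regions,
decline prevalence 17/44 at 3 months and 11/37 at 12 months among the 37
with follow-up, 7 missing 12-month scores, 27/44 patients on scanner A.

* **Template network**: distance-penalized random geometric weights over
  points on a sphere split into hemispheres, with an inter-hemispheric
  backbone guaranteeing connectedness. A left "anterior temporal" subset is
  the resection target; each region pair carries a base probability that
  its streamlines cross the mask (near 1 inside the target, decaying with
  distance outside).
* **Patients**: per-pair counts are overdispersed negative binomial draws
  around the template; each streamline is flagged by its pair's crossing
  probability.
* **Planted effect**: labels are drawn first at the configured prevalence;
  each of the `n_signal_regions` signal regions — placed by greedy max-min
  distance among non-resected regions, because clustered signal regions
  would share neighbours that aggregate (and noise-average) their
  severities and thereby out-signal the planted regions themselves — then
  receives an independent per-patient resection severity
  $0.25 + 0.08\,(d\,y + \varepsilon)$, $\varepsilon \sim N(0,1)$, applied
  to all streamlines touching that region. By the Gaussian location-shift
  construction this is *exactly* a logistic model of the label on the
  standardized signal features with coefficient $d$ per feature, and the
  decliner/non-decliner separation of each signal feature is $d$ pooled
  SDs (verified empirically to ≈ 2 at $d = 2$ after the full
  log/mask/ratio pipeline). Independent severities per region keep the five
  features from collapsing into one collinear direction, so recovery tests
  can ask that all five be found.
* **Scores backwards**: decliners receive a pre-minus-post drop ≥ 4,
  non-decliners < 4, so dichotomization reproduces the labels exactly —
  also a tested invariant. Clinical covariates get modest label-linked
  shifts mirroring the published group contrasts (e.g. higher laterality
  index and earlier onset in decliners).
* **Batch effects** are applied to the assembled graph features
  (scale then shift per scanner, defaults 1.2× and +0.5); clinical
  covariates are scanner-independent. The 12-month label is drawn from a
  logistic model tied to the 3-month label (coefficient 2), with the
  intercept solved so the marginal rate among followed-up patients matches
  the target.

What the generator does **not** emulate: spatial geometry beyond region
labels, tractography biases (false-positive bundles, SIFT filtering),
scanner differences in the *network* itself (batch effects enter at the
feature level), and registration/mask-drawing error. Passing recovery tests
therefore demonstrates the statistical machinery, not robustness to those
imaging realities.

## Problem sizes used by the test suite

Parameter recovery runs 10 generator seeds at $n = 120$, $d = 2$, five
signal regions, with threshold-averaged features; null calibration runs 20
seeds at the study size $n = 44$, $d = 0$, with 1000 permutations; the
leakage guard shuffles labels 10 times on one cohort. These sizes were
chosen to give the moment and rank checks adequate power while keeping a
full suite run on one CPU in the tens of minutes.

## Limitations

* The selection-optimism property above applies to any use of the reported
  maximum-AUC model on small cohorts.
* Least-squares (not logistic) selection follows the protocol; with heavy
  imbalance the intercept absorbs prevalence but coefficients are not
  class-calibrated.
* ComBat before cross-validation leaks batch summary statistics across
  folds; `combat_harmonize()` can be applied within folds by the user, at
  the cost of departing from the reference ordering.
* The reliable-change criterion is operationalized as a raw drop ≥ 4
  points; the classical standardized reliable-change index is not computed
  (the scorer is pluggable via the `threshold` argument).
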