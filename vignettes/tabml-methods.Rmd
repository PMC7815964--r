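---
title: "Methods: automated discovery on incomplete biomedical tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated discovery on incomplete biomedical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tabml)
```

## The problem

A typical biomedical cohort table has one row per donor, numeric predictor
columns from one or more assays, and a two-class outcome. Three properties
make naive modelling unreliable: whole assay panels are missing for
subsets of donors; classes are often heavily unbalanced; and the feature
count can exceed the sample count. `tabml` automates a discovery loop
designed around those three properties. This vignette documents the
methods, the tunable parameters, the numerical choices, and what the
package's own tests do and do not demonstrate.

## Missingness resampling

Define a sample's *signature* as its set of observed (non-missing)
features. Samples with identical signatures form groups that partition the
cohort (`compute_signatures()`). The engine then computes the
*intersection closure* of the signature feature sets: the family of all
distinct non-empty intersections over every non-empty subset of
signatures. Each member feature set, paired with the maximal set of
samples observing all of it, is a *resample* — a complete submatrix of the
original table (`generate_resamples()`).

The closure is computed by a worklist algorithm: new sets are intersected
against all known sets until a fixed point, with hash-based
deduplication. The family size is worst-case exponential in the number of
signatures, so a cap (default 10,000 sets) turns pathological
fragmentation into an explicit resource error suggesting coarser assay
blocks. Correctness is tested against an independent oracle that
enumerates all `2^k - 1` subset intersections over bitmasks.

Parameters:

* `min_samples` (default 15) and `min_features` (default 2): resamples
  smaller than this are dropped *after* the closure is complete. Below
  roughly 15 samples, 10-fold cross-validation folds degenerate.
* `filter_resamples(test_fraction, min_test_samples)`: drops resamples
  whose prospective holdout would hold fewer than `min_test_samples`
  donors (`floor(n × test_fraction) < min_test`), the guard against
  overly optimistic estimates from tiny holdout sets.

Resample identity is content-based: a 64-bit FNV-1a digest of the sorted
feature names, so ids are stable across runs, platforms, and row/column
orderings.

## The modelling harness

For each resample × algorithm unit:

1. **Partition** (`partition()`): stratified; each class contributes
   `round(count × train_fraction)` samples to training (default 0.75),
   clamped so both splits retain both classes. The partition seed is
   derived from the resample id only, so *all algorithms of a resample
   share the same split* and their metrics are directly comparable.
2. **Tuning** (`tune_and_train()`): repeated stratified k-fold CV (default
   10 folds × 3 repeats; folds dealt cyclically within class after a
   seeded shuffle, so fold class proportions stay within one sample of the
   split's). For every hyperparameter grid point, preprocessing is refit
   inside each fold on the fold's training part, the candidate is fit and
   scored on the held-out fold, and metrics are averaged over all
   folds × repeats. The winner maximizes the selection metric (default
   AUROC; ties keep the first grid row). The final model is refit on the
   full training split.
3. **Holdout evaluation** (`evaluate_holdout()`): the untouched test split
   is scored exactly once, after tuning.

The "validation set" of the classical three-way split is realized as the
CV folds within the training split; no third physical split is made. This
keeps small resamples usable and is the standard construction when a
dedicated validation cohort is unavailable.

**Seed policy.** A master seed plus stable string labels (resample id,
algorithm id, repeat, fold) are hashed into per-unit seeds
(`derive_seed()`). Consequences worth stating: adding an algorithm never
perturbs another algorithm's results; serial and parallel execution are
bit-identical; and any unit can be reproduced in isolation.

**Preprocessing order** is fixed: impute → near-zero-variance drop →
correlated drop → center → scale, regardless of the order requested.
Median imputation precedes variance screening so that a feature's variance
is judged on the imputed column actually used downstream. Correlated-drop
is greedy on the absolute correlation matrix: repeatedly take the worst
pair above the threshold (default 0.9) and drop the member with the larger
mean absolute correlation to all remaining features; exact ties drop the
later column in dataset order, making the procedure deterministic.

**Algorithm registry.** Ten families, each a native estimator behind a
uniform fit/predict-probability surface with a small default grid (at most
five candidates per parameter): shrinkage *diagonal* discriminant analysis
(pooled per-feature variances shrunk toward their median — usable at
p ≫ n, standing in for the shrinkage/high-dimensional discriminant
family), elastic-net logistic regression, linear-kernel SVM, naive Bayes,
random forest, a k-nearest-neighbour posterior, bagged trees, gradient
boosted trees, a single-hidden-layer neural net, and a neural net on PCA
scores. Boosted logistic regression is represented by the gradient-boosted
tree family rather than a separate LogitBoost implementation.

## Metrics

All metrics are implemented in the package with explicit tie and
degenerate-case handling:

* **AUROC** in concordance form — the probability a random positive
  outscores a random negative, ties credited ½ — computed from rank sums.
  This equals the trapezoidal area over the tie-grouped ROC curve and is
  exact, not grid-dependent.
* **prAUC** as average precision, `Σ (R_k − R_{k−1}) P_k` over distinct
  thresholds in descending order. Trapezoidal interpolation of precision
  is deliberately avoided (it is biased upward); implementations that use
  it will differ slightly. A constant-score classifier collapses the curve
  to one point and the area equals the prevalence exactly.
* **LogLoss** with probabilities clamped to `[1e-15, 1 − 1e-15]`.
* Degenerate situations (no positive predictions, a single-class truth
  vector) yield `NA` markers; `rank_models()` sorts them last
  deterministically. Nothing is silently coerced to 0.

Each implementation is verified against an independent brute-force oracle
(pairwise concordance loops, direct summation) to 1e-12 on hundreds of
random vectors, including heavily tied ones.

## Variable importance

`variable_importance()` uses the model's native importance when the family
defines one — absolute standardized coefficients for linear and
discriminant models, split-gain totals for tree ensembles — and
permutation importance otherwise: the mean drop in training AUROC over
`n_permutations` (default 25) seeded shuffles of one feature column. AUROC
drop is preferred over accuracy drop for robustness under class imbalance.
Raw values are shifted to minimum 0 and scaled to maximum 100; the raw
column is retained because min-max scaling destroys cross-model
comparability of magnitudes (aggregation uses the scaled scores, matching
how such tables are usually displayed). If the largest raw importance is
below a tolerance the table is flagged `no_signal` rather than scaled into
meaningless ranks. One caveat stated plainly: permutation importance on
the *training* split inherits the model's overfit, so raw drops on pure
noise are small but not exactly zero; the tests bound them rather than
assert zero.

## Exploratory statistics

**Correlation** (`correlation_matrix()`): pairwise-complete observations
per pair with the per-pair n reported; pairs under `min_pairs` (default 3)
and all pairs involving constant features are `NA`, flagged, and excluded
from the high-correlation report (display threshold 0.75, independent of
the preprocessing drop threshold 0.9).

**Clustering** (`hierarchical_cluster()`): standard agglomerative
clustering (Euclidean or 1 − r distance; average, complete, or Ward
linkage) over samples or features, requiring an explicitly imputed grid.
Ties resolve toward the smaller leaf index; leaf order is the tree's
natural order without optimal-leaf reordering, so output is deterministic.
The distance/linkage defaults (euclidean, average) are exposed as
arguments rather than asserted as canonical.

**SAM** (`sam_test()`): two-class unpaired moderated statistic
`d_i = (mean₂ − mean₁) / (s_i + s₀)` with `s_i` the pooled standard error.
The fudge factor `s₀` is, by default, the percentile of the `s`
distribution (grid 0, 5, …, 100) minimizing the coefficient of variation
of the within-window spread of `d` across equal-count windows of `s` —
the stabilisation that keeps low-variance features from dominating; the
median of `s` is the documented fallback. The null is built from balanced
label permutations: exhaustively enumerated when at most `n_permutations`
distinct assignments exist, otherwise seeded sampling. Calling at
threshold delta scans outward from the center of the expected order
statistics `d̄₍ᵢ₎`: the upper cut is `d̄₍ᵢ₎ + delta` at the first upper-half
crossing (symmetrically below), and every feature beyond a cut is called.

The FDR estimate is the median permutation false-call count divided by the
observed call count, where each permutation's false calls are the *larger*
of two counts: its values beyond the observed cuts, and the calls the
identical delta-band procedure would make on that permutation. The two
counts fail in opposite regimes — cut-based counting under-estimates on
null data at small call counts (the cuts sit just beyond the observed
draw's own extremes), procedure-based counting under-estimates under a
strong alternative (permutations are judged only against their own
deviations) — so the pessimistic maximum is reported. Users should still
treat FDR estimates at very small call counts as coarse: with integer
false-call counts and a median over permutations, values are quantized and
decay along a constant-call-count plateau. This is an intrinsic property
of permutation FDR, not an implementation artifact.

## Synthetic data: what it emulates, and what it does not

`make_classification_data()` draws class-conditional Gaussians with equal
identity covariance: informative features get a between-class mean shift
of `effect_size` at unit variance, so single-feature discrimination has
the closed form AUROC `Φ(effect/√2)` — the analytic anchor used by the
calibration tests. Block missingness removes whole feature blocks for
seeded random donor subsets, reproducing the multi-assay patterns that
make intersection resampling worthwhile. Ground truth (the informative
feature names) travels as a dataset attribute and a sidecar file, so
generated CSVs are schema-identical to real inputs and recovery tests
never peek at generator internals.

Archetype presets fix the study conditions: `sisa` 534 × 14 complete and
near-balanced; `cyclists` 195 × 90 at 120:75 with two feature blocks
(18 features missing for 20% of donors, 12 for 30%) giving 8.0% missing
cells; `vast` 72 × 60 at 26:46 with two blocks (20 and 16 features, each
missing for 35%) giving 20.8%; `zeller` 184 × 800; `lihc` 424 × 300 at
374:50. Block sizes and fractions were chosen once, by expectation
arithmetic, to land the published missingness rates of the archetype
studies; effect sizes and informative counts are generic "moderate
signal" choices.

What the generator does *not* emulate: heavy-tailed or skewed marginals,
realistic correlation spectra, batch structure, or label noise. Passing
tests on these archetypes therefore demonstrate the *engine* (no leakage,
correct closure, calibrated null behaviour, recoverable planted signal) —
they do not certify performance claims on any real dataset.

## Problem sizes in the test suite

The suite runs its statistical checks at deliberately modest sizes chosen
to keep each property estimable with comfortable margins: 200 random
missingness patterns (≤ 12 signatures, ≤ 10 features) for closure
equivalence; 500 random vectors (n ≤ 100) for the metric oracles; 20
seeded runs at 200 × 50 for null calibration (mean holdout AUROC within
0.45–0.55); 20 seeded runs at 200 × 100 with 5 informative features at
effect size 1.5 for signal recovery (holdout AUROC ≥ 0.85, ≥ 4/5 true
features in the aggregate importance top 10); and 20 runs of 500-feature
SAM grids with 25 features shifted by 2 sd. Cross-validation in tests uses
3–5 folds × 1 repeat; the package defaults (10 × 3) are what an analysis
would use.

## Known limitations

* Binary outcomes only; no multiclass or regression, no ensembling.
* The closure cap makes extremely fragmented missingness (hundreds of
  distinct signatures) an explicit error rather than a long computation.
* Permutation FDR in SAM is coarse at very small call counts (see above).
* Hyperparameter grids are small by design; the harness optimizes
  comparability and reproducibility, not leaderboard performance.
* Serialized models embed a format version and a prediction fingerprint;
  loading verifies both, but models are not interchangeable with other
  platforms' serialized formats.
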