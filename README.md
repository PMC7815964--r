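# tabml

Automated machine-learning discovery for binary-outcome biomedical feature
tables.

Biomedical tables — clinical panels, flow-cytometry immunophenotyping,
serology, microbiome and expression matrices — routinely arrive with three
pathologies that break a naive modelling workflow: **missing cells**
(assays not run for every donor), **class imbalance** (many patients, few
controls), and **high dimensionality** (far more features than samples).
`tabml` automates the full discovery loop on such tables for researchers
who want reliable, leakage-free model comparisons without writing the
harness themselves.

## What it does

1. **Missingness resampling.** Each sample has an *observed-feature
   signature* (the set of features measured for it). The engine computes
   the intersection closure of these signatures — every distinct non-empty
   intersection over every subset of signatures — and pairs each feature
   set with the maximal sample set observing all of it. Every such
   *resample* is a complete (no missing cells) submatrix, so datasets with
   block-structured missingness can be modelled without imputation or
   row-deletion compromises. Resamples whose prospective holdout would
   fall below a minimum size (`floor(n × test_fraction) < min_test`) are
   filtered out.
2. **Leakage-safe automated modelling.** For each resample × algorithm:
   stratified train/holdout partition (default 75/25, shared across
   algorithms so models are comparable), repeated stratified k-fold
   cross-validation (default 10 × 3) with grid hyperparameter tuning,
   preprocessing (median imputation, centering, scaling, near-zero
   variance and correlated-feature removal) refit inside every fold on
   that fold's training part only, and a single holdout evaluation after
   the winning hyperparameters are fixed. The registry covers ten
   algorithm families (shrinkage discriminant, penalized logistic
   regression, linear SVM, naive Bayes, random forest, k-NN, bagged
   trees, gradient boosting, neural nets with and without PCA feature
   extraction).
3. **Unified metrics.** Accuracy, sensitivity, specificity, precision,
   recall, F1, AUROC (concordance form, ties ½: the probability a random
   positive outscores a random negative), precision-recall AUC (average
   precision, `Σ (R_k − R_{k−1}) P_k` — not trapezoidal, which is biased),
   and LogLoss (`−mean(y log p + (1−y) log(1−p))`, clamped at 1e-15).
   Degenerate cases return explicit `NA` markers that sort last in
   rankings, never a silent 0. Under heavy class imbalance the harness
   recommends ranking by prAUC rather than AUROC.
4. **Feature selection.** Variable importance per model — native scores
   (standardized coefficient magnitudes, split-gain totals) where the
   family defines them, permutation importance (mean training-AUROC drop
   over seeded shuffles) otherwise — min-max scaled to 0–100 and
   aggregated across models.
5. **Exploratory statistics.** Pairwise-complete correlation matrices,
   agglomerative hierarchical clustering (for batch-effect inspection),
   and two-class SAM: the moderated statistic `d = Δmean / (s + s₀)` with
   the fudge factor `s₀` chosen to stabilise low-variance features, and a
   permutation-calibrated FDR per calling threshold.
6. **Synthetic archetypes.** Seeded generators reproduce the shapes that
   matter for testing: a 534 × 14 complete clinical table, block-missing
   multi-assay tables at 8% and 21% missing cells, a wide 184 × 800
   table, and a 374:50 unbalanced table — so every stage is testable
   without downloading anything.

## Worked example

```r
library(tabml)

# a 150 x 30 cohort: 4 informative features (standardized mean difference
# 1.5), one assay block (f025-f030) unmeasured for 40% of donors
d <- make_classification_data(synth_spec(
  n_samples = 150, n_features = 30, n_informative = 4, effect_size = 1.5,
  seed = 42,
  missingness = list(list(features = sprintf("f%03d", 25:30), fraction = 0.4))))
d
#> <ml_dataset> 150 samples x 30 features
#>   outcome 'outcome': control=75, case=75 (positive: case)
#>   missing cells: 360 (8.0%)

cfg <- experiment_config(c("sdda", "rf", "naive_bayes"), cv = cv_plan(5, 1),
                         mulset = list(min_samples = 20, min_features = 2),
                         seed = 42)
res <- run_experiment(d, cfg)
rank_models(res, metric = "auroc", split = "cv")[1:3, c(1:3, 6:7)]
#>   rank algorithm_id      resample_id     value other_split_value
#> 1    1         sdda 4a54a1298900a129 1.0000000         0.9318182
#> 2    2  naive_bayes 4a54a1298900a129 0.9904762         0.9090909
#> 3    3         sdda 14e628998b722899 0.9787764         1.0000000
```

The missingness pattern yields two resamples (the 24-feature grid over all
150 donors and the full 30-feature grid over the ~90 fully measured ones);
each algorithm is tuned and evaluated on both. `value` is the
cross-validated AUROC on the training split, `other_split_value` the
holdout AUROC measured once after tuning. The best model's holdout metrics
and importance table:

```r
best <- res[[which.max(vapply(res, function(r) r$cv_metrics$auroc, 0))]]
best$holdout_metrics
#> <metric_set> accuracy=0.826 sensitivity=0.909 specificity=0.750
#>   precision=0.769 recall=0.909 f1=0.833 auroc=0.932 prauc=0.924 logloss=0.456
head(best$importances, 5)
#>   feature     score       raw       method
#> 1    f004 100.00000 1.9710369 model_native
#> 2    f001  90.60828 1.7880363 model_native
#> 3    f002  85.59724 1.6903949 model_native
#> 4    f003  78.64870 1.5550005 model_native
#> 5    f012  28.24857 0.5729389 model_native
```

All four planted informative features (`f001`–`f004`) top the importance
table; the first noise feature trails far behind.

A command-line wrapper with `simulate`, `resamples`, `train`, `evaluate`,
`importance`, and `explore` subcommands is installed at
`inst/cli/tabml` (see `tabml::cli_main()`).

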