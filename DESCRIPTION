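Package: tabml
Title: Automated Machine-Learning Discovery for Biomedical Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated knowledge-discovery engine for binary-outcome
    biomedical feature tables. Generates all complete submatrices
    ("resamples") of a table with missing cells by intersecting per-sample
    observed-feature signatures, runs leakage-safe preprocessing and
    repeated stratified cross-validated training with grid hyperparameter
    tuning over a registry of classification algorithms, evaluates models
    on an untouched holdout split with a unified metric layer (accuracy,
    sensitivity, specificity, precision, recall, F1, AUROC, precision-recall
    AUC, log loss), scores variable importance scaled 0-100, and provides
    exploratory statistics: pairwise correlation, hierarchical clustering,
    and significance analysis of microarrays (SAM) with permutation-based
    FDR. Includes seeded generators for clinical, multi-assay block-missing,
    wide, and class-imbalanced dataset archetypes, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    graphics,
    grDevices,
    e1071,
    randomForest,
    rpart,
    nnet,
    glmnet,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    caret,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
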