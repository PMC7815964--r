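fit_on <- function(d, alg = "sdda", seed = 1) {
  sp <- partition(d, partition_spec(seed = seed))
  fit <- tune_and_train(sp$train, alg, quick_cv(3), seed = seed)
  list(fit = fit, train = sp$train)
}

test_that("a feature that determines the outcome scores 100", {
  set.seed(1)
  x <- matrix(rnorm(200 * 6), 200, 6)
  outcome <- ifelse(x[, 3] > 0, "case", "control")
  d <- ml_dataset(x, outcome = outcome, positive_class = "case")
  f <- fit_on(d)
  vi <- variable_importance(f$fit$model_handle, f$train)
  expect_equal(vi$feature[1], "f3")
  expect_equal(vi$score[1], 100)
  expect_false(attr(vi, "no_signal"))
})

test_that("pure-noise features yield small permutation importances", {
  # on outcome-independent features the per-feature AUROC drop stays near
  # zero (bounded by model-overfit noise); the no-signal flag fires when the
  # largest raw value falls below the tolerance
  for (seed in 1:5) {
    d <- make_classification_data(synth_spec(100, 8, n_informative = 0,
                                             seed = seed))
    f <- fit_on(d, seed = seed)
    vi <- variable_importance(f$fit$model_handle, f$train,
                              method = "permutation", n_permutations = 10,
                              seed = seed)
    expect_true(all(vi$raw < 0.2))  # no feature moves training AUROC much
    vi_flag <- variable_importance(f$fit$model_handle, f$train,
                                   method = "permutation",
                                   n_permutations = 10, seed = seed,
                                   tol = 0.5)
    expect_true(attr(vi_flag, "no_signal"))
    expect_true(all(vi_flag$score == 0))
  }
})

test_that("permutation importance is exactly reproducible given a seed", {
  d <- make_classification_data(synth_spec(60, 5, n_informative = 1,
                                           effect_size = 2, seed = 2))
  f <- fit_on(d, seed = 2)
  v1 <- variable_importance(f$fit$model_handle, f$train,
                            method = "permutation", n_permutations = 5,
                            seed = 77)
  v2 <- variable_importance(f$fit$model_handle, f$train,
                            method = "permutation", n_permutations = 5,
                            seed = 77)
  expect_identical(v1, v2)
  expect_error(variable_importance(f$fit$model_handle, f$train,
                                   method = "permutation",
                                   n_permutations = 1), ">= 2")
})

test_that("a duplicated informative feature shares the top native ranks", {
  set.seed(3)
  x <- matrix(rnorm(150 * 5), 150, 5)
  x[, 2] <- x[, 1]
  outcome <- ifelse(x[, 1] + rnorm(150, sd = 0.5) > 0, "case", "control")
  d <- ml_dataset(x, outcome = outcome, positive_class = "case")
  f <- fit_on(d)
  vi <- variable_importance(f$fit$model_handle, f$train)
  expect_setequal(vi$feature[1:2], c("f1", "f2"))
  expect_equal(vi$raw[1], vi$raw[2], tolerance = 1e-9)
})

test_that("min-max scaling preserves raw ranking", {
  d <- make_classification_data(synth_spec(120, 10, n_informative = 3,
                                           effect_size = 1.5, seed = 4))
  f <- fit_on(d, seed = 4)
  vi <- variable_importance(f$fit$model_handle, f$train)
  expect_equal(order(-vi$score), order(-vi$raw))
  expect_equal(max(vi$score), 100)
  expect_true(all(vi$score >= 0))
})

test_that("aggregate_importance reduces to the single-model table", {
  d <- make_classification_data(synth_spec(100, 6, n_informative = 2,
                                           effect_size = 2, seed = 5))
  f <- fit_on(d, seed = 5)
  vi <- variable_importance(f$fit$model_handle, f$train)
  agg1 <- aggregate_importance(list(vi))
  expect_equal(agg1$mean_score,
               vi$score[match(agg1$feature, vi$feature)])
  agg2 <- aggregate_importance(list(vi, vi))
  expect_equal(agg2$mean_score, agg1$mean_score)
  expect_true(all(agg2$n_models == 2))
})

test_that("importance is invariant to feature order", {
  d <- make_classification_data(synth_spec(80, 6, n_informative = 2,
                                           effect_size = 2, seed = 6))
  f1 <- fit_on(d, seed = 6)
  vi1 <- variable_importance(f1$fit$model_handle, f1$train)
  perm <- c(4, 2, 6, 1, 3, 5)
  d2 <- ml_dataset(d$values[, perm], outcome = as.character(d$outcome),
                   positive_class = "case", sample_ids = d$sample_ids)
  f2 <- fit_on(d2, seed = 6)
  vi2 <- variable_importance(f2$fit$model_handle, f2$train)
  m <- match(vi1$feature, vi2$feature)
  expect_equal(vi1$raw, vi2$raw[m], tolerance = 1e-9)
})
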