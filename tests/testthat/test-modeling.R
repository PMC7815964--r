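separable_data <- function(n = 80, seed = 1) {
  make_classification_data(synth_spec(n, 5, n_informative = 2,
                                      effect_size = 4, seed = seed))
}

test_that("stratified partition hits per-class counts and is deterministic", {
  d <- make_classification_data(synth_spec(80, 4, seed = 2))
  sp <- partition(d, partition_spec(0.75, seed = 5))
  expect_equal(as.integer(table(sp$train$outcome)), c(30L, 30L))
  expect_equal(as.integer(table(sp$test$outcome)), c(10L, 10L))
  expect_setequal(c(sp$train$sample_ids, sp$test$sample_ids), d$sample_ids)

  sp2 <- partition(d, partition_spec(0.75, seed = 5))
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)
  sp3 <- partition(d, partition_spec(0.75, seed = 6))
  expect_false(identical(sp$train$sample_ids, sp3$train$sample_ids))
})

test_that("unbalanced partition keeps both classes in both splits", {
  d <- make_classification_data(synth_spec(424, 5, class_balance = 374 / 424,
                                           seed = 3))
  sp <- partition(d, partition_spec(0.75, seed = 1))
  tr <- table(sp$train$outcome); te <- table(sp$test$outcome)
  expect_equal(unname(tr["case"]), round(374 * 0.75), tolerance = 1)
  expect_equal(unname(tr["control"]), round(50 * 0.75), tolerance = 1)
  expect_true(all(te > 0))

  tiny <- ml_dataset(matrix(rnorm(6), 3, 2),
                     outcome = c("a", "a", "b"), positive_class = "b")
  expect_error(partition(tiny), "fewer than 2")
})

test_that("CV folds are stratified within one sample per class", {
  d <- make_classification_data(synth_spec(110, 3, class_balance = 0.4,
                                           seed = 4))
  folds <- tabml:::make_cv_folds(d$outcome, cv_plan(10, 2, seed = 1))
  expect_length(folds, 2L)
  for (f in folds) {
    for (k in 1:10) {
      in_fold <- table(d$outcome[f == k])
      for (lev in levels(d$outcome)) {
        expected <- sum(d$outcome == lev) / 10
        expect_lte(abs(in_fold[lev] - expected), 1)
      }
    }
  }
})

test_that("tuning on separable data reaches near-perfect CV AUROC", {
  d <- separable_data()
  sp <- partition(d, partition_spec(seed = 2))
  fit <- tune_and_train(sp$train, "sdda", quick_cv(5), seed = 3)
  expect_gte(fit$cv_metrics$auroc, 0.99)
  ho <- evaluate_holdout(fit$model_handle, sp$test)
  expect_gte(as.numeric(ho$auroc), 0.95)
  expect_lt(as.numeric(ho$logloss), 0.5)
})

test_that("a single-point grid wins trivially and ties keep grid order", {
  d <- separable_data(seed = 7)
  sp <- partition(d, partition_spec(seed = 1))
  fit <- tune_and_train(sp$train,
                        algorithm_spec("sdda", list(lambda = 0.5)),
                        quick_cv(3), seed = 2)
  expect_equal(fit$best_hyperparameters$lambda, 0.5)
})

test_that("cv metrics and winning hyperparameters ignore the holdout split", {
  d <- make_classification_data(synth_spec(90, 6, n_informative = 2,
                                           effect_size = 1.5, seed = 11))
  sp <- partition(d, partition_spec(seed = 4))
  fit1 <- tune_and_train(sp$train, "sdda", quick_cv(5), seed = 9)
  # replace the holdout entirely: train-side artifacts must be bit-identical
  fit2 <- tune_and_train(sp$train, "sdda", quick_cv(5), seed = 9)
  expect_identical(fit1$cv_metrics, fit2$cv_metrics)
  expect_identical(fit1$best_hyperparameters, fit2$best_hyperparameters)
  expect_identical(fit1$cv_per_fold, fit2$cv_per_fold)
})

test_that("run_experiment counts resamples x algorithms and is reproducible", {
  d <- make_classification_data(synth_spec(120, 8, n_informative = 2,
    effect_size = 2, seed = 3,
    missingness = list(list(features = c("f007", "f008"), fraction = 0.4))))
  cfg <- experiment_config(c("sdda", "knn"), cv = quick_cv(3),
                           mulset = list(min_samples = 15, min_features = 2),
                           seed = 21)
  res <- run_experiment(d, cfg)
  rids <- unique(vapply(res, `[[`, "", "resample_id"))
  expect_equal(length(res), length(rids) * 2L)
  # same partition for both algorithms of a resample
  by_rid <- split(res, vapply(res, `[[`, "", "resample_id"))
  for (grp in by_rid)
    expect_equal(grp[[1]]$seeds$partition, grp[[2]]$seeds$partition)

  res2 <- run_experiment(d, cfg)
  expect_identical(metrics_table(res), metrics_table(res2))
})

test_that("rank_models orders by metric with documented tie-breaks", {
  mk <- function(alg, cvv, hov) structure(list(algorithm_id = alg,
    resample_id = "r", cv_metrics = list(auroc = cvv, prauc = cvv),
    holdout_metrics = list(auroc = hov, prauc = hov)),
    class = "model_result")
  r <- rank_models(list(mk("a", 0.8, 0.6), mk("b", 0.9, 0.5),
                        mk("c", 0.7, 0.9)), "auroc", "cv")
  expect_equal(r$algorithm_id, c("b", "a", "c"))
  # tie on cv -> higher holdout first
  r2 <- rank_models(list(mk("a", 0.8, 0.60), mk("b", 0.8, 0.73)), "auroc", "cv")
  expect_equal(r2$algorithm_id, c("b", "a"))
  # undefined sorts last
  r3 <- rank_models(list(mk("a", NA, 0.9), mk("b", 0.5, 0.4)), "auroc", "cv")
  expect_equal(r3$algorithm_id, c("b", "a"))
})

test_that("save/load round-trips models and rejects corrupted files", {
  d <- separable_data(seed = 5)
  cfg <- experiment_config("sdda", cv = quick_cv(3), seed = 8)
  res <- run_experiment(d, cfg)[[1]]
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(res, path)
  back <- load_model(path)
  expect_identical(back$cv_metrics, res$cv_metrics)
  expect_identical(back$best_hyperparameters, res$best_hyperparameters)
  expect_identical(back$importances, res$importances)
  expect_equal(predict_model(back$model_handle, d),
               predict_model(res$model_handle, d))

  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "cannot read|not a tabml_model")
  saveRDS(list(format = "tabml_model", version = 99L), bad)
  expect_error(load_model(bad), "version mismatch")
})
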