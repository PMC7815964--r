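# Experiment harness: stratified partitioning, repeated stratified k-fold
# cross-validation with grid tuning, holdout evaluation, ranking, and model
# round-tripping. The holdout split is created before any tuning and touched
# exactly once, after the winning hyperparameters are fixed.

#' Partition specification
#' @param train_fraction proportion of each class assigned to training
#'   (default 0.75).
#' @param seed integer seed making the split reproducible.
#' @return A `partition_spec`.
#' @export
partition_spec <- function(train_fraction = 0.75, seed = 1L) {
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  structure(list(train_fraction = train_fraction, stratified = TRUE,
                 seed = as.integer(seed)), class = "partition_spec")
}

#' Cross-validation plan
#' @param n_folds folds per repeat (default 10).
#' @param n_repeats repeats (default 3).
#' @param seed integer seed for fold assignment.
#' @return A `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 3L, seed = 1L) {
  assert_that(n_folds >= 2, "need at least 2 folds")
  assert_that(n_repeats >= 1, "need at least 1 repeat")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), stratified = TRUE,
                 seed = as.integer(seed)), class = "cv_plan")
}

#' Stratified train/holdout partition
#'
#' Each class contributes `round(class_count * train_fraction)` samples to
#' the training split (clamped so both splits keep at least one sample of
#' each class); the rest form the holdout. Deterministic given the seed.
#'
#' @param dataset an `ml_dataset` with at least 2 samples per class.
#' @param spec a [partition_spec()].
#' @return List with `train` and `test` (`ml_dataset`s).
#' @export
partition <- function(dataset, spec = partition_spec()) {
  counts <- table(dataset$outcome)
  if (any(counts < 2))
    stop(sprintf("class '%s' has fewer than 2 samples",
                 names(counts)[which(counts < 2)[1]]), call. = FALSE)
  set.seed(spec$seed)
  train_idx <- integer()
  for (lev in levels(dataset$outcome)) {
    idx <- which(dataset$outcome == lev)
    n_tr <- round(length(idx) * spec$train_fraction)
    n_tr <- max(1L, min(length(idx) - 1L, n_tr))
    train_idx <- c(train_idx, sort(sample(idx, n_tr)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(n_samples(dataset)), train_idx)
  list(train = subset_dataset(dataset, samples = train_idx),
       test = subset_dataset(dataset, samples = test_idx))
}

# Stratified fold assignment: per repeat, a vector of fold ids. Within each
# class members are shuffled and folds dealt cyclically, so every fold's
# class proportions are within one sample of the split's.
make_cv_folds <- function(outcome, plan) {
  lapply(seq_len(plan$n_repeats), function(r) {
    set.seed(derive_seed(plan$seed, "cv_fold", r))
    fold <- integer(length(outcome))
    for (lev in levels(outcome)) {
      idx <- which(outcome == lev)
      fold[sample(idx)] <- rep_len(seq_len(plan$n_folds), length(idx))
    }
    fold
  })
}

as_algorithm_spec <- function(a, selection_metric = "auroc") {
  if (inherits(a, "algorithm_spec")) a
  else algorithm_spec(a, selection_metric = selection_metric)
}

#' Tune hyperparameters by repeated stratified CV and fit the final model
#'
#' For every grid point, preprocessing is refit inside each fold on the
#' fold's training part only, the candidate model is fit and evaluated on
#' the held-out fold, and metrics are averaged over all folds x repeats.
#' The grid point maximizing the selection metric wins (ties keep the first
#' grid row); the final model is refit on the full training split with the
#' winning hyperparameters and a preprocessing plan learned from the full
#' training split.
#'
#' @param train an `ml_dataset` (training split; may contain missing cells if
#'   `impute_median` is among the steps).
#' @param alg an [algorithm_spec()] or registry id string.
#' @param cv a [cv_plan()].
#' @param steps preprocessing steps (see [fit_preprocess()]).
#' @param seed integer seed for fold assignment and stochastic fits.
#' @return A list with `model_handle`, `cv_metrics` (means), `cv_metrics_sd`,
#'   `cv_per_fold` (data.frame), `best_hyperparameters`, `grid_summary`.
#' @export
tune_and_train <- function(train, alg, cv = cv_plan(),
                           steps = c("impute_median", "center", "scale"),
                           seed = 1L) {
  alg <- as_algorithm_spec(alg)
  assert_that(nlevels(droplevels(train$outcome)) == 2,
              "both classes must be present in the training split")
  grid <- expand.grid(alg$grid, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  cv <- structure(c(cv[setdiff(names(cv), "seed")],
                    list(seed = derive_seed(seed, "folds"))), class = "cv_plan")
  folds <- make_cv_folds(train$outcome, cv)

  eval_point <- function(g) {
    rows <- list()
    for (r in seq_len(cv$n_repeats)) {
      for (f in seq_len(cv$n_folds)) {
        va_idx <- which(folds[[r]] == f)
        tr_idx <- setdiff(seq_len(n_samples(train)), va_idx)
        if (!length(va_idx)) next
        fold_train <- subset_dataset(train, samples = tr_idx)
        fold_val <- subset_dataset(train, samples = va_idx)
        plan <- fit_preprocess(fold_train, steps)
        xtr <- apply_preprocess(plan, fold_train)
        xva <- apply_preprocess(plan, fold_val)
        fit_seed <- derive_seed(seed, "fit", g, r, f)
        model <- alg$entry$fit(xtr$values, xtr$outcome,
                               as.list(grid[g, , drop = FALSE]), fit_seed)
        scores <- clamp01(alg$entry$predict(model, xva$values))
        ms <- metric_set(scores, xva$outcome, train$positive_class)
        rows[[length(rows) + 1L]] <-
          data.frame(grid_point = g, repeat_ = r, fold = f,
                     t(vapply(ms[metric_names()], as.numeric, 0)))
      }
    }
    do.call(rbind, rows)
  }

  per_fold <- vector("list", nrow(grid))
  failed <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    per_fold[[g]] <- tryCatch(eval_point(g), error = function(e) {
      warning(sprintf("grid point %d of '%s' failed: %s", g,
                      alg$algorithm_id, conditionMessage(e)), call. = FALSE)
      NULL
    })
    failed[g] <- is.null(per_fold[[g]])
  }
  if (all(failed))
    stop(sprintf("all grid points failed for algorithm '%s'",
                 alg$algorithm_id), call. = FALSE)

  sel <- vapply(seq_len(nrow(grid)), function(g) {
    if (failed[g]) return(-Inf)
    v <- per_fold[[g]][[alg$selection_metric]]
    if (all(is.na(v))) -Inf else mean(v, na.rm = TRUE)
  }, 0)
  best_g <- which.max(sel)  # first maximum = first in grid order
  best_fold <- per_fold[[best_g]]
  cv_mean <- lapply(metric_names(), function(m) {
    v <- best_fold[[m]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(cv_mean) <- metric_names()
  cv_sd <- lapply(metric_names(), function(m) stats::sd(best_fold[[m]], na.rm = TRUE))
  names(cv_sd) <- metric_names()

  plan <- fit_preprocess(train, steps)
  xtr <- apply_preprocess(plan, train)
  final_seed <- derive_seed(seed, "final", best_g)
  model <- alg$entry$fit(xtr$values, xtr$outcome,
                         as.list(grid[best_g, , drop = FALSE]), final_seed)
  fp_idx <- seq_len(min(10L, n_samples(train)))
  handle <- structure(list(
    algorithm_id = alg$algorithm_id, model = model, plan = plan,
    positive_class = train$positive_class,
    levels = levels(train$outcome),
    feature_names = train$feature_names,
    fingerprint_x = train$values[fp_idx, , drop = FALSE]),
    class = "model_handle")
  list(model_handle = handle, cv_metrics = cv_mean, cv_metrics_sd = cv_sd,
       cv_per_fold = best_fold,
       best_hyperparameters = as.list(grid[best_g, , drop = FALSE]),
       grid_summary = data.frame(grid, selection = sel, failed = failed))
}

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

#' Predict positive-class probabilities with a fitted model handle
#' @param handle a `model_handle`.
#' @param data an `ml_dataset` containing the handle's features.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_model <- function(handle, data) {
  entry <- algorithm_registry(handle$algorithm_id)[[1]]
  x <- apply_preprocess(handle$plan, data)
  clamp01(entry$predict(handle$model, x$values))
}

#' Evaluate a tuned model on the untouched holdout split
#'
#' @param handle a `model_handle` from [tune_and_train()].
#' @param test the holdout `ml_dataset` (never used during tuning).
#' @return A [metric_set()] of holdout performance.
#' @export
evaluate_holdout <- function(handle, test) {
  metric_set(predict_model(handle, test), test$outcome, handle$positive_class)
}

#' Experiment configuration
#'
#' @param algorithms character vector of registry ids or list of
#'   [algorithm_spec()]s.
#' @param partition a [partition_spec()] (seed is overridden by the derived
#'   per-resample seed inside [run_experiment()]).
#' @param cv a [cv_plan()].
#' @param preprocess_steps steps for [fit_preprocess()].
#' @param selection_metric tuning metric. With minority-class prevalence
#'   below 0.25 the harness warns that `"prauc"` ranks models more honestly.
#' @param mulset `NULL` to model the table as-is, or a list with
#'   `min_samples`, `min_features`, `min_test_samples` to enumerate
#'   missingness resamples first.
#' @param importance `"auto"`, `"permutation"`, or `"none"`.
#' @param seed master seed; all per-unit seeds are derived from it.
#' @param n_workers parallel workers for the resample x algorithm grid
#'   (results are identical for any worker count).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(algorithms,
                              partition = partition_spec(),
                              cv = cv_plan(),
                              preprocess_steps = c("impute_median", "center",
                                                   "scale"),
                              selection_metric = "auroc",
                              mulset = NULL,
                              importance = c("auto", "permutation", "none"),
                              seed = 1L, n_workers = 1L) {
  importance <- match.arg(importance)
  algorithms <- lapply(algorithms, as_algorithm_spec,
                       selection_metric = selection_metric)
  structure(list(algorithms = algorithms, partition = partition, cv = cv,
                 preprocess_steps = preprocess_steps,
                 selection_metric = selection_metric, mulset = mulset,
                 importance = importance, seed = as.integer(seed),
                 n_workers = as.integer(n_workers)),
            class = "experiment_config")
}

#' Run the full automated experiment
#'
#' When missingness resampling is enabled, enumerates the complete
#' submatrices of the table first and crosses them with every configured
#' algorithm; otherwise the table itself is the single resample. For each
#' unit: stratified partition (shared across algorithms of the same
#' resample, so models are comparable), CV grid tuning on the training
#' split, one holdout evaluation, and variable-importance scoring. Unit
#' seeds are derived by stable hashing, so serial and parallel execution
#' give identical results and adding an algorithm never perturbs others.
#'
#' @param dataset an `ml_dataset`.
#' @param config an [experiment_config()].
#' @return List of `model_result` objects.
#' @export
run_experiment <- function(dataset, config) {
  prevalence <- mean(dataset$outcome == dataset$positive_class)
  if (min(prevalence, 1 - prevalence) < 0.25 &&
      config$selection_metric == "auroc")
    warning(sprintf(paste("minority-class prevalence is %.2f;",
                          "AUROC can look optimistic on unbalanced data --",
                          "consider selection_metric = 'prauc'"),
                    min(prevalence, 1 - prevalence)), call. = FALSE)

  if (!is.null(config$mulset)) {
    ms <- config$mulset
    sigs <- compute_signatures(dataset)
    resamples <- generate_resamples(sigs,
                                    min_samples = ms$min_samples %||% 15L,
                                    min_features = ms$min_features %||% 2L)
    if (!is.null(ms$min_test_samples))
      resamples <- filter_resamples(resamples,
                                    test_fraction = 1 - config$partition$train_fraction,
                                    min_test_samples = ms$min_test_samples)
    assert_that(length(resamples) > 0, "no resamples survive the size filters")
  } else {
    resamples <- list(new_resample(dataset$feature_names, dataset$sample_ids))
  }

  units <- expand.grid(ri = seq_along(resamples),
                       ai = seq_along(config$algorithms))
  run_unit <- function(u) {
    rs <- resamples[[units$ri[u]]]
    alg <- config$algorithms[[units$ai[u]]]
    t0 <- proc.time()[["elapsed"]]
    tryCatch({
      sub <- if (is.null(config$mulset)) dataset
             else extract_submatrix(dataset, rs)
      pspec <- partition_spec(config$partition$train_fraction,
                              seed = derive_seed(config$seed, "partition",
                                                 rs$resample_id))
      split <- partition(sub, pspec)
      tune_seed <- derive_seed(config$seed, "tune", rs$resample_id,
                               alg$algorithm_id)
      fit <- tune_and_train(split$train, alg, config$cv,
                            steps = config$preprocess_steps, seed = tune_seed)
      holdout <- evaluate_holdout(fit$model_handle, split$test)
      importances <- if (config$importance != "none")
        variable_importance(fit$model_handle, split$train,
                            method = config$importance,
                            seed = derive_seed(config$seed, "importance",
                                               rs$resample_id,
                                               alg$algorithm_id))
      structure(list(
        algorithm_id = alg$algorithm_id, resample_id = rs$resample_id,
        n_train = n_samples(split$train), n_test = n_samples(split$test),
        n_features = rs$n_features,
        cv_metrics = fit$cv_metrics, cv_metrics_sd = fit$cv_metrics_sd,
        cv_per_fold = fit$cv_per_fold, holdout_metrics = holdout,
        best_hyperparameters = fit$best_hyperparameters,
        importances = importances, model_handle = fit$model_handle,
        timing = proc.time()[["elapsed"]] - t0,
        seeds = list(master = config$seed, partition = pspec$seed,
                     tune = tune_seed)),
        class = "model_result")
    }, error = function(e) {
      warning(sprintf("unit (resample %s, algorithm %s) failed: %s",
                      substr(rs$resample_id, 1, 8), alg$algorithm_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }

  results <- if (config$n_workers > 1L &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(units)), run_unit,
                       mc.cores = config$n_workers, mc.set.seed = FALSE)
  } else {
    lapply(seq_len(nrow(units)), run_unit)
  }
  results <- Filter(Negate(is.null), results)
  assert_that(length(results) > 0, "every model failed; no results to return")
  results
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s on resample %s (%d train / %d test)\n",
              x$algorithm_id, substr(x$resample_id, 1, 8), x$n_train, x$n_test))
  cat(sprintf("  cv auroc %.3f  holdout auroc %.3f\n",
              x$cv_metrics$auroc, as.numeric(x$holdout_metrics$auroc)))
  invisible(x)
}

#' Rank model results by a metric
#'
#' Descending order on the chosen split's metric; ties broken by the same
#' metric on the other split, then by algorithm id alphabetically.
#' Undefined (NA) metrics sort last.
#'
#' @param results list of `model_result`.
#' @param metric one of the metric names (default `"auroc"`).
#' @param split `"cv"` or `"holdout"`.
#' @return data.frame of ranked models with both splits' metric values.
#' @export
rank_models <- function(results, metric = "auroc",
                        split = c("cv", "holdout")) {
  split <- match.arg(split)
  assert_that(metric %in% metric_names(), sprintf("unknown metric '%s'", metric))
  get_val <- function(r, s)
    as.numeric((if (s == "cv") r$cv_metrics else r$holdout_metrics)[[metric]])
  primary <- vapply(results, get_val, 0, s = split)
  secondary <- vapply(results, get_val, 0,
                      s = if (split == "cv") "holdout" else "cv")
  alg <- vapply(results, `[[`, "", "algorithm_id")
  rid <- vapply(results, `[[`, "", "resample_id")
  key1 <- ifelse(is.na(primary), -Inf, primary)
  key2 <- ifelse(is.na(secondary), -Inf, secondary)
  ord <- order(-key1, -key2, alg)
  data.frame(rank = seq_along(ord), algorithm_id = alg[ord],
             resample_id = rid[ord],
             metric = metric, split = split,
             value = primary[ord], other_split_value = secondary[ord],
             stringsAsFactors = FALSE)
}

#' Tidy metric table for a set of results
#'
#' One row per model x metric x split, suitable for TSV export and box
#' plots (per-fold CV values are available via `cv_per_fold` on each
#' result).
#'
#' @param results list of `model_result`.
#' @return data.frame with columns algorithm_id, resample_id, split, metric,
#'   value.
#' @export
metrics_table <- function(results) {
  rows <- lapply(results, function(r) {
    rbind(
      data.frame(algorithm_id = r$algorithm_id, resample_id = r$resample_id,
                 split = "cv", metric = metric_names(),
                 value = vapply(r$cv_metrics[metric_names()], as.numeric, 0),
                 stringsAsFactors = FALSE),
      data.frame(algorithm_id = r$algorithm_id, resample_id = r$resample_id,
                 split = "holdout", metric = metric_names(),
                 value = vapply(r$holdout_metrics[metric_names()], as.numeric, 0),
                 stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

MODEL_FORMAT <- "tabml_model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a model result
#'
#' The container embeds a format name and version plus a prediction
#' fingerprint (up to 10 training rows and their predicted probabilities);
#' [load_model()] verifies both and errors on mismatch, so silent model
#' corruption cannot pass unnoticed.
#'
#' @param result a `model_result`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `model_result`.
#' @export
save_model <- function(result, path) {
  fp_x <- result$model_handle$fingerprint_x
  fp_data <- ml_dataset(fp_x,
                        outcome = rep(result$model_handle$levels,
                                      length.out = nrow(fp_x)),
                        positive_class = result$model_handle$positive_class)
  expected <- predict_model(result$model_handle, fp_data)
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_FORMAT_VERSION,
               result = result, fingerprint = list(x = fp_x,
                                                   expected = expected)),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read model file '%s': %s (expected format %s v%d)",
                 path, conditionMessage(e), MODEL_FORMAT,
                 MODEL_FORMAT_VERSION), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT))
    stop(sprintf("not a %s file: %s", MODEL_FORMAT, path), call. = FALSE)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop(sprintf("model format version mismatch: file has %s, this build reads %d",
                 obj$version, MODEL_FORMAT_VERSION), call. = FALSE)
  fp <- obj$fingerprint
  fp_data <- ml_dataset(fp$x,
                        outcome = rep(obj$result$model_handle$levels,
                                      length.out = nrow(fp$x)),
                        positive_class = obj$result$model_handle$positive_class)
  actual <- predict_model(obj$result$model_handle, fp_data)
  if (!isTRUE(all.equal(actual, fp$expected, tolerance = 1e-8)))
    stop("model integrity check failed: fingerprint predictions differ",
         call. = FALSE)
  obj$result
}
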