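# Variable-importance scoring, 0-100 scaled, with cross-model aggregation.

#' Variable importance for a fitted model
#'
#' `method = "auto"` uses the algorithm's native importance when its family
#' defines one (absolute standardized coefficients for linear/discriminant
#' models, split-gain totals for tree ensembles) and falls back to
#' permutation importance otherwise. Permutation importance of a feature is
#' the mean drop in training AUROC over `n_permutations` seeded shuffles of
#' that feature's column. Raw values are shifted to a minimum of 0 and
#' scaled so the maximum is 100; when the largest raw importance is below
#' `tol` the table is flagged `no_signal` and all scores are 0.
#'
#' @param handle a `model_handle` from [tune_and_train()].
#' @param train the training `ml_dataset` the model was fit on.
#' @param method `"auto"` or `"permutation"`.
#' @param n_permutations shuffles per feature for the permutation method
#'   (default 25; must be >= 2).
#' @param seed integer seed for the shuffles.
#' @param tol raw-importance threshold below which the table is flagged as
#'   carrying no signal.
#' @return data.frame (class `importance_table`) with columns feature,
#'   score (0-100), raw, method; attribute `no_signal`.
#' @export
variable_importance <- function(handle, train,
                                method = c("auto", "permutation"),
                                n_permutations = 25L, seed = 1L,
                                tol = 1e-8) {
  method <- match.arg(method)
  entry <- algorithm_registry(handle$algorithm_id)[[1]]
  x <- apply_preprocess(handle$plan, train)
  if (method == "auto" && !is.null(entry$importance)) {
    raw <- entry$importance(handle$model, x$values)
    raw <- raw[colnames(x$values)]
    names(raw) <- colnames(x$values)
    used <- "model_native"
  } else {
    assert_that(n_permutations >= 2,
                "permutation importance needs n_permutations >= 2")
    baseline <- roc_auc(clamp01(entry$predict(handle$model, x$values)),
                        x$outcome, handle$positive_class)$auroc
    raw <- vapply(seq_len(ncol(x$values)), function(j) {
      set.seed(derive_seed(seed, "perm_imp", colnames(x$values)[j]))
      drops <- vapply(seq_len(n_permutations), function(b) {
        xp <- x$values
        xp[, j] <- xp[sample(nrow(xp)), j]
        baseline - roc_auc(clamp01(entry$predict(handle$model, xp)),
                           x$outcome, handle$positive_class)$auroc
      }, 0)
      mean(drops)
    }, 0)
    names(raw) <- colnames(x$values)
    used <- "permutation"
  }
  raw[is.na(raw)] <- 0
  shifted <- raw - min(raw)
  no_signal <- max(shifted) < tol
  score <- if (no_signal) rep(0, length(raw)) else 100 * shifted / max(shifted)
  out <- data.frame(feature = names(raw), score = score, raw = raw,
                    method = used, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  attr(out, "no_signal") <- no_signal
  class(out) <- c("importance_table", class(out))
  out
}

#' Aggregate importance tables across models
#'
#' Features dropped by a model's preprocessing contribute no entry for that
#' model. Scores are the 0-100 scaled values (comparable across models by
#' construction), summarised as mean score, mean rank, and how often the
#' feature lands in each model's top k.
#'
#' @param results list of `model_result` (with `importances`) or of
#'   `importance_table`s.
#' @param top_k cutoff for the models-in-top-k count (default 10).
#' @return data.frame ordered by mean score descending: feature, mean_score,
#'   mean_rank, n_models, models_in_top_k.
#' @export
aggregate_importance <- function(results, top_k = 10L) {
  tables <- lapply(results, function(r)
    if (inherits(r, "model_result")) r$importances else r)
  tables <- Filter(Negate(is.null), tables)
  assert_that(length(tables) >= 1, "no importance tables to aggregate")
  rows <- do.call(rbind, lapply(seq_along(tables), function(i) {
    tb <- tables[[i]]
    data.frame(model = i, feature = tb$feature, score = tb$score,
               rank = rank(-tb$score, ties.method = "min"),
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(rows, rows$feature), function(d) {
    data.frame(feature = d$feature[1], mean_score = mean(d$score),
               mean_rank = mean(d$rank), n_models = nrow(d),
               models_in_top_k = sum(d$rank <= top_k),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$mean_score, agg$feature), ]
  rownames(agg) <- NULL
  agg
}
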