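# Performance metrics with explicit tie and degenerate-case handling.
# Degenerate cases return NA_real_ (the "undefined" marker) so that ranking
# can deterministically sort them last; they are never silently 0.

#' Confusion-matrix metrics for hard class predictions
#'
#' Standard 2x2 definitions. `precision` is undefined (`NA`) when there are
#' no positive predictions; `specificity` is undefined when there are no
#' actual negatives; `F1` is undefined when precision or recall is.
#'
#' @param predicted_labels,true_labels equal-length label vectors.
#' @param positive_class the positive label.
#' @return Named list: accuracy, sensitivity, specificity, precision,
#'   recall, f1.
#' @export
confusion_metrics <- function(predicted_labels, true_labels, positive_class) {
  assert_that(length(predicted_labels) == length(true_labels) &&
                length(true_labels) >= 1, "label vectors must have equal length >= 1")
  classes <- unique(as.character(true_labels))
  if (length(classes) == 2) {
    bad <- setdiff(unique(as.character(predicted_labels)),
                   c(classes, positive_class))
    assert_that(length(bad) == 0,
                paste("predicted label outside the two classes:",
                      paste(bad, collapse = ", ")))
  }
  y <- as.character(true_labels) == positive_class
  p <- as.character(predicted_labels) == positive_class
  tp <- sum(p & y); fp <- sum(p & !y); fn <- sum(!p & y); tn <- sum(!p & !y)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(accuracy = (tp + tn) / length(y), sensitivity = sens,
       specificity = spec, precision = prec, recall = sens, f1 = f1)
}

#' ROC curve and AUROC
#'
#' AUROC is computed in concordance form: the probability that a randomly
#' chosen positive sample outscores a randomly chosen negative one, with
#' ties credited 1/2 (equivalent to the trapezoidal area over the
#' tie-grouped ROC curve). Undefined (`NA`) when either class is absent.
#'
#' @param scores positive-class probabilities or any monotone score.
#' @param true_labels class labels.
#' @param positive_class the positive label.
#' @return List with `curve` (data.frame threshold/fpr/tpr swept over
#'   distinct thresholds) and `auroc`.
#' @export
roc_auc <- function(scores, true_labels, positive_class) {
  y <- as.character(true_labels) == positive_class
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0)
    return(list(curve = NULL, auroc = NA_real_))
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), 0)
  fp <- vapply(thr, function(t) sum(!y & scores >= t), 0)
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(curve = curve, auroc = auroc)
}

#' Precision-recall curve and prAUC
#'
#' The area is the average-precision summation \eqn{\sum_k (R_k - R_{k-1})
#' P_k} over distinct score thresholds in descending order — not a
#' trapezoid, since linear interpolation of precision is biased. For a
#' constant-score classifier the curve collapses to one point and the area
#' equals the prevalence. Undefined (`NA`) with zero positives.
#'
#' @inheritParams roc_auc
#' @return List with `curve` (threshold/recall/precision) and `prauc`.
#' @export
pr_auc <- function(scores, true_labels, positive_class) {
  y <- as.character(true_labels) == positive_class
  n_pos <- sum(y)
  if (n_pos == 0) return(list(curve = NULL, prauc = NA_real_))
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(y & scores >= t), 0)
  np <- vapply(thr, function(t) sum(scores >= t), 0)
  recall <- tp / n_pos
  precision <- tp / np
  prauc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = thr, recall = recall,
                          precision = precision),
       prauc = prauc)
}

#' Logarithmic loss
#'
#' \eqn{-\mathrm{mean}(y \log p + (1-y)\log(1-p))} with probabilities
#' clamped to `[eps, 1 - eps]` so that hard 0/1 scores stay finite.
#'
#' @inheritParams roc_auc
#' @param eps clamp bound (default 1e-15).
#' @return Non-negative number.
#' @export
log_loss <- function(scores, true_labels, positive_class, eps = 1e-15) {
  assert_that(all(scores >= 0 & scores <= 1), "scores must be in [0, 1]")
  y <- as.numeric(as.character(true_labels) == positive_class)
  p <- pmin(pmax(scores, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Full metric set for probability predictions
#'
#' Hard labels are obtained at the 0.5 probability threshold; ROC/PR/LogLoss
#' use the probabilities directly.
#'
#' @inheritParams roc_auc
#' @param threshold probability cutoff for hard predictions.
#' @return Named list of class `metric_set`: accuracy, sensitivity,
#'   specificity, precision, recall, f1, auroc, prauc, logloss, plus
#'   `positive_class`, `n_positive`, `n_negative`.
#' @export
metric_set <- function(scores, true_labels, positive_class, threshold = 0.5) {
  y <- as.character(true_labels) == positive_class
  classes <- unique(as.character(true_labels))
  negative <- setdiff(classes, positive_class)
  negative <- if (length(negative)) negative[1] else paste0("not_", positive_class)
  pred <- ifelse(scores >= threshold, positive_class, negative)
  cm <- confusion_metrics(pred, true_labels, positive_class)
  out <- c(cm, list(
    auroc = roc_auc(scores, true_labels, positive_class)$auroc,
    prauc = pr_auc(scores, true_labels, positive_class)$prauc,
    logloss = log_loss(scores, true_labels, positive_class),
    positive_class = positive_class,
    n_positive = sum(y), n_negative = sum(!y)))
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  nm <- c("accuracy", "sensitivity", "specificity", "precision", "recall",
          "f1", "auroc", "prauc", "logloss")
  v <- vapply(x[nm], function(z) if (is.na(z)) NA_real_ else z, 0)
  cat("<metric_set>", paste(sprintf("%s=%.3f", nm, v), collapse = " "), "\n")
  invisible(x)
}

metric_names <- function() c("accuracy", "sensitivity", "specificity",
                             "precision", "recall", "f1", "auroc", "prauc",
                             "logloss")
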