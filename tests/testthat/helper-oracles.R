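# Independent brute-force oracles used to check the package's metric and
# closure implementations. Deliberately written as plain loops, sharing no
# code with the implementations they verify.

oracle_auroc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  total / (length(pos) * length(neg))
}

oracle_average_precision <- function(scores, labels, positive) {
  y <- labels == positive
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  r_prev <- 0
  for (t in thresholds) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (y[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    r <- tp / sum(y)
    p <- tp / (tp + fp)
    ap <- ap + (r - r_prev) * p
    r_prev <- r
  }
  ap
}

oracle_logloss <- function(scores, labels, positive, eps = 1e-15) {
  total <- 0
  for (i in seq_along(scores)) {
    p <- min(max(scores[i], eps), 1 - eps)
    total <- total + if (labels[i] == positive) -log(p) else -log(1 - p)
  }
  total / length(scores)
}

# Intersection closure by exhaustive subset enumeration over bitmasks.
# masks: integer vector, one bit per feature. Returns the sorted distinct
# non-empty AND-combinations over every non-empty subset.
oracle_closure_masks <- function(masks) {
  k <- length(masks)
  out <- integer(0)
  for (s in seq_len(2^k - 1)) {
    acc <- NULL
    for (j in seq_len(k)) {
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L)
        acc <- if (is.null(acc)) masks[j] else bitwAnd(acc, masks[j])
    }
    if (acc != 0L) out <- c(out, acc)
  }
  sort(unique(out))
}

feature_set_to_mask <- function(features, all_features) {
  sum(bitwShiftL(1L, match(features, all_features) - 1L))
}
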