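# Exploratory statistics: pairwise correlation, hierarchical clustering for
# batch-effect inspection, and SAM (significance analysis of microarrays)
# with permutation-calibrated FDR.

#' Pairwise-complete correlation matrix
#'
#' Each pair's coefficient is computed on the rows where both features are
#' observed; pairs with fewer than `min_pairs` shared observations, and all
#' pairs involving a constant feature, are marked undefined (`NA`).
#'
#' @param dataset an `ml_dataset` with >= 2 features.
#' @param method `"pearson"` or `"spearman"`.
#' @param min_pairs minimum shared observations per pair (default 3).
#' @param report_threshold absolute correlation above which a pair is listed
#'   in `high_pairs` (display threshold, default 0.75; independent of the
#'   preprocessing drop threshold).
#' @return List of class `correlation_result`: `r` (feature x feature),
#'   `n_used`, `method`, `high_pairs` (data.frame feature_a/feature_b/r),
#'   `constant_features`.
#' @export
correlation_matrix <- function(dataset, method = c("pearson", "spearman"),
                               min_pairs = 3L, report_threshold = 0.75) {
  method <- match.arg(method)
  assert_that(n_features(dataset) >= 2, "need at least 2 features")
  x <- dataset$values
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = method))
  n_used <- crossprod(!is.na(x))
  r[n_used < min_pairs] <- NA_real_
  sds <- apply(x, 2, stats::sd, na.rm = TRUE)
  constant <- colnames(x)[is.na(sds) | sds == 0]
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  diag(r) <- ifelse(colnames(x) %in% constant, NA_real_, 1)
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > report_threshold,
               arr.ind = TRUE)
  high <- data.frame(feature_a = rownames(r)[idx[, 1]],
                     feature_b = colnames(r)[idx[, 2]],
                     r = r[idx], stringsAsFactors = FALSE)
  high <- high[order(-abs(high$r)), ]
  rownames(high) <- NULL
  structure(list(r = r, n_used = n_used, method = method, high_pairs = high,
                 constant_features = constant,
                 report_threshold = report_threshold),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d features, method %s, %d pair(s) with |r| > %g\n",
              ncol(x$r), x$method, nrow(x$high_pairs), x$report_threshold))
  invisible(x)
}

#' Agglomerative hierarchical clustering of samples or features
#'
#' Requires a complete grid (impute first). Distances are Euclidean or
#' correlation-based (1 - r); linkage is average, complete, or Ward.
#' Merge order follows the standard agglomerative procedure with ties
#' resolved toward the smaller leaf index; leaf order is the tree's natural
#' order (no optimal-leaf reordering), so results are deterministic.
#'
#' @param dataset an `ml_dataset` with no missing cells.
#' @param distance `"euclidean"` or `"correlation"`.
#' @param linkage `"average"`, `"complete"`, or `"ward"`.
#' @param axis cluster `"samples"` (rows) or `"features"` (columns).
#' @return List of class `clustering_result`: `merge`, `height`, `order`,
#'   `labels`, plus the underlying `hclust` object.
#' @export
hierarchical_cluster <- function(dataset,
                                 distance = c("euclidean", "correlation"),
                                 linkage = c("average", "complete", "ward"),
                                 axis = c("samples", "features")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  axis <- match.arg(axis)
  if (anyNA(dataset$values))
    stop("grid contains missing cells; impute first (e.g. fit_preprocess with impute_median)",
         call. = FALSE)
  x <- if (axis == "samples") dataset$values else t(dataset$values)
  assert_that(nrow(x) >= 2, "need at least 2 objects to cluster")
  d <- if (distance == "euclidean") stats::dist(x)
       else stats::as.dist(1 - suppressWarnings(stats::cor(t(x))))
  hc <- stats::hclust(d, method = switch(linkage, average = "average",
                                         complete = "complete",
                                         ward = "ward.D2"))
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = rownames(x), distance = distance,
                 linkage = linkage, axis = axis, hclust = hc),
            class = "clustering_result")
}

#' Cut a clustering into k groups
#' @param clustering a `clustering_result`.
#' @param k number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

# Two-sample moderated statistic: d_i = (mean2 - mean1) / (s_i + s0) with
# s_i the pooled standard error of the mean difference.
sam_d_stat <- function(x, is2, s0) {
  x1 <- x[!is2, , drop = FALSE]; x2 <- x[is2, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  ss <- colSums(sweep(x1, 2, m1)^2) + colSums(sweep(x2, 2, m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (m2 - m1) / (s + s0), s = s)
}

# Fudge-factor selection: over candidate percentiles 0, 5, ..., 100 of the
# s_i distribution, pick the s0 minimizing the coefficient of variation of
# the MAD of d across equal-count windows of s_i.
sam_choose_s0 <- function(x, is2) {
  s <- sam_d_stat(x, is2, s0 = 0)$s
  p <- length(s)
  probs <- seq(0, 1, by = 0.05)
  candidates <- stats::quantile(s, probs, names = FALSE)
  n_win <- max(2L, min(10L, floor(p / 5)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_win, labels = FALSE)
  cv <- vapply(candidates, function(s0) {
    d <- sam_d_stat(x, is2, s0)$d
    v <- vapply(split(d, win), stats::mad, 0)
    if (mean(v) <= 0) return(Inf)
    stats::sd(v) / mean(v)
  }, 0)
  if (all(!is.finite(cv))) return(list(s0 = stats::median(s), percentile = NA_real_))
  best <- which.min(cv)
  list(s0 = candidates[best], percentile = probs[best])
}

#' Significance analysis of microarrays (two-class, unpaired)
#'
#' Computes the moderated difference statistic \eqn{d_i = (\bar{x}_{i2} -
#' \bar{x}_{i1}) / (s_i + s_0)} per feature, calibrates the expected order
#' statistics of \eqn{d} under label permutations, and reports, for a grid
#' of thresholds delta, the features called significant together with a
#' permutation-based FDR estimate: the median permutation false-call count
#' divided by the observed call count. The false-call count per permutation
#' is the larger of (a) its values beyond the observed cuts and (b) the
#' calls the identical delta-band procedure would make on that permutation;
#' either count alone under-estimates the FDR in a different regime, so the
#' pessimistic maximum is reported. Estimates at very small call counts are
#' integer-quantized and remain noisy — a known property of permutation
#' FDR.
#'
#' When all distinct balanced label assignments number at most
#' `n_permutations` they are enumerated exactly; otherwise `n_permutations`
#' seeded random permutations are drawn.
#'
#' @param dataset an `ml_dataset` with a complete grid and >= 2 samples per
#'   class; the outcome provides the two groups (group 2 = positive class).
#' @param n_permutations permutation budget (default 100).
#' @param seed integer seed for sampled permutations.
#' @param s0_rule `"cv_min"` (percentile of the s distribution minimizing
#'   the coefficient of variation of d across s windows; the default) or
#'   `"median"`.
#' @param deltas optional increasing vector of thresholds; default is an
#'   even grid over the observed |d - dbar| range.
#' @param n_deltas grid size when `deltas` is not given.
#' @return List of class `sam_table`: `features` (feature, d, s),
#'   `s0`, `s0_percentile`, `expected` (sorted null order statistics),
#'   `delta_table` (delta, called, false_median, fdr), `n_permutations`,
#'   `exhaustive`.
#' @export
sam_test <- function(dataset, n_permutations = 100L, seed = 1L,
                     s0_rule = c("cv_min", "median"), deltas = NULL,
                     n_deltas = 30L) {
  s0_rule <- match.arg(s0_rule)
  assert_that(!anyNA(dataset$values), "SAM requires a complete grid; impute first")
  is2 <- dataset$outcome == dataset$positive_class
  assert_that(sum(is2) >= 2 && sum(!is2) >= 2,
              "need at least 2 samples per class")
  x <- dataset$values
  n <- nrow(x)

  s0_sel <- if (s0_rule == "cv_min") sam_choose_s0(x, is2)
            else list(s0 = stats::median(sam_d_stat(x, is2, 0)$s),
                      percentile = NA_real_)
  obs <- sam_d_stat(x, is2, s0_sel$s0)

  n2 <- sum(is2)
  n_distinct <- choose(n, n2)
  assert_that(n_distinct >= 2, "fewer than 2 distinct label permutations exist")
  exhaustive <- n_distinct <= n_permutations
  perm_sets <- if (exhaustive) {
    asplit(utils::combn(n, n2), 2)
  } else {
    set.seed(derive_seed(seed, "sam_perm"))
    lapply(seq_len(n_permutations), function(b) sample(n, n2))
  }
  null_d <- vapply(perm_sets, function(idx) {
    g <- logical(n); g[idx] <- TRUE
    sort(sam_d_stat(x, g, s0_sel$s0)$d)
  }, numeric(ncol(x)))
  expected <- rowMeans(null_d)  # expected order statistics of d under null

  d_sorted <- sort(obs$d)
  diff_up <- d_sorted - expected
  diff_low <- expected - d_sorted
  # scan outward from the center of the expected order statistics: the
  # upper cut comes from the upper half, the lower cut from the lower half
  upper_half <- expected >= 0
  if (is.null(deltas)) {
    deltas <- seq(0, max(abs(d_sorted - expected)), length.out = n_deltas)
  }
  delta_table <- do.call(rbind, lapply(deltas, function(delta) {
    above <- which(diff_up > delta & upper_half)
    below <- which(diff_low > delta & !upper_half)
    # cuts at the band edge (expected order statistic +/- delta) at the
    # first crossing, scanning outward from the center
    cut_up <- if (length(above)) min(expected[above] + delta) else Inf
    cut_low <- if (length(below)) max(expected[below] - delta) else -Inf
    called_mask <- obs$d >= cut_up | obs$d <= cut_low
    called <- sum(called_mask)
    # two permutation false-call counts: permuted values beyond the
    # observed cuts, and the identical calling procedure applied to each
    # permuted d vector; the larger (more pessimistic) median is used,
    # since each count alone under-estimates in a different regime
    fc_cut <- vapply(seq_len(ncol(null_d)), function(b)
      sum(null_d[, b] >= cut_up | null_d[, b] <= cut_low), 0)
    fc_proc <- vapply(seq_len(ncol(null_d)), function(b) {
      db <- null_d[, b]  # already sorted
      ab <- which(db - expected > delta & upper_half)
      bl <- which(expected - db > delta & !upper_half)
      cu <- if (length(ab)) min(expected[ab] + delta) else Inf
      cl <- if (length(bl)) max(expected[bl] - delta) else -Inf
      sum(db >= cu | db <= cl)
    }, 0)
    false_median <- max(stats::median(fc_cut), stats::median(fc_proc))
    fdr <- if (called == 0) NA_real_ else min(1, false_median / called)
    data.frame(delta = delta, called = called, false_median = false_median,
               fdr = fdr, cut_up = cut_up, cut_low = cut_low)
  }))
  rownames(delta_table) <- NULL
  structure(list(
    features = data.frame(feature = dataset$feature_names, d = obs$d,
                          s = obs$s, row.names = NULL,
                          stringsAsFactors = FALSE),
    s0 = s0_sel$s0, s0_percentile = s0_sel$percentile, expected = expected,
    delta_table = delta_table, n_permutations = length(perm_sets),
    exhaustive = exhaustive), class = "sam_table")
}

#' Features called significant at a given delta
#' @param sam a `sam_table`.
#' @param delta threshold; the nearest row of the delta table at or below it
#'   is not used — cuts are recomputed exactly for this delta.
#' @return Character vector of called feature names.
#' @export
sam_called <- function(sam, delta) {
  d_sorted <- sort(sam$features$d)
  upper_half <- sam$expected >= 0
  above <- which(d_sorted - sam$expected > delta & upper_half)
  below <- which(sam$expected - d_sorted > delta & !upper_half)
  cut_up <- if (length(above)) min(sam$expected[above] + delta) else Inf
  cut_low <- if (length(below)) max(sam$expected[below] - delta) else -Inf
  sam$features$feature[sam$features$d >= cut_up | sam$features$d <= cut_low]
}

#' @export
print.sam_table <- function(x, ...) {
  cat(sprintf("<sam_table> %d features, s0 = %.4g (percentile %s), %d permutation(s)%s\n",
              nrow(x$features), x$s0,
              ifelse(is.na(x$s0_percentile), "n/a", x$s0_percentile),
              x$n_permutations, if (x$exhaustive) " (exhaustive)" else ""))
  invisible(x)
}
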