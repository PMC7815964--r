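# Leakage-safe preprocessing: every statistic is learned on the training
# split only and then applied unchanged to any other split.

#' Learn a preprocessing plan from a training split
#'
#' Supported steps, applied in the fixed order impute_median, drop_nzv,
#' drop_correlated, center, scale regardless of the order requested.
#' Statistics (medians, means, standard deviations, dropped features) come
#' exclusively from `train`; [apply_preprocess()] replays them on any split.
#'
#' @param train an `ml_dataset` (the training split).
#' @param steps character subset of `c("impute_median", "drop_nzv",
#'   "drop_correlated", "center", "scale")`.
#' @param correlated_threshold absolute-correlation cutoff for
#'   `drop_correlated` (default 0.9).
#' @param correlated_method correlation type for `drop_correlated`.
#' @return A `preprocess_plan`.
#' @export
fit_preprocess <- function(train,
                           steps = c("impute_median", "center", "scale"),
                           correlated_threshold = 0.9,
                           correlated_method = c("pearson", "spearman")) {
  valid <- c("impute_median", "drop_nzv", "drop_correlated", "center", "scale")
  bad <- setdiff(steps, valid)
  assert_that(length(bad) == 0,
              paste("unknown preprocessing step(s):", paste(bad, collapse = ", ")))
  assert_that(n_samples(train) >= 1, "training split is empty")
  correlated_method <- match.arg(correlated_method)
  steps <- valid[valid %in% steps]  # canonical order
  x <- train$values
  dropped <- data.frame(feature = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_feature <- function(nm, why) {
    dropped <<- rbind(dropped, data.frame(feature = nm, reason = why,
                                          stringsAsFactors = FALSE))
    x <<- x[, setdiff(colnames(x), nm), drop = FALSE]
  }

  medians <- NULL
  if ("impute_median" %in% steps) {
    all_missing <- colnames(x)[colSums(!is.na(x)) == 0]
    if (length(all_missing)) {
      warning("dropping feature(s) entirely missing in the training split: ",
              paste(all_missing, collapse = ", "))
      drop_feature(all_missing, "all missing in training split")
    }
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
    x <- impute_with(x, medians)
  }
  if ("drop_nzv" %in% steps) {
    sds <- apply(x, 2, stats::sd, na.rm = TRUE)
    zv <- colnames(x)[is.na(sds) | sds == 0]
    if (length(zv)) drop_feature(zv, "zero variance")
  }
  if ("drop_correlated" %in% steps) {
    if (anyNA(x))
      stop("drop_correlated requires a complete grid; request impute_median first",
           call. = FALSE)
    corr_drop <- find_correlated_matrix(x, threshold = correlated_threshold,
                                        method = correlated_method)
    if (length(corr_drop))
      drop_feature(corr_drop,
                   sprintf("|r| > %g with retained feature", correlated_threshold))
  }
  means <- sds <- NULL
  if ("center" %in% steps) means <- colMeans(x, na.rm = TRUE)
  if ("scale" %in% steps) {
    assert_that(n_samples(train) >= 2, "scale requires at least 2 samples")
    sds <- apply(x, 2, stats::sd, na.rm = TRUE)
    # zero-sd features that survived (drop_nzv not requested): center only
    sds[is.na(sds) | sds == 0] <- 1
  }
  structure(list(steps = steps, retained = colnames(x), dropped = dropped,
                 medians = medians, means = means, sds = sds,
                 correlated_threshold = correlated_threshold,
                 correlated_method = correlated_method),
            class = "preprocess_plan")
}

impute_with <- function(x, medians) {
  for (j in colnames(x)) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- medians[[j]]
  }
  x
}

#' Apply a learned preprocessing plan to a dataset
#'
#' @param plan a `preprocess_plan` from [fit_preprocess()].
#' @param data an `ml_dataset` whose features must include every feature the
#'   plan retained.
#' @return The transformed `ml_dataset`, restricted to the plan's retained
#'   features.
#' @export
apply_preprocess <- function(plan, data) {
  missing <- setdiff(plan$retained, data$feature_names)
  assert_that(length(missing) == 0,
              paste("dataset lacks feature(s) required by the plan:",
                    paste(missing, collapse = ", ")))
  d <- subset_dataset(data, features = plan$retained)
  x <- d$values
  if ("impute_median" %in% plan$steps)
    x <- impute_with(x, plan$medians[plan$retained])
  if ("center" %in% plan$steps)
    x <- sweep(x, 2, plan$means[plan$retained], "-")
  if ("scale" %in% plan$steps)
    x <- sweep(x, 2, plan$sds[plan$retained], "/")
  d$values <- x
  d
}

#' @export
print.preprocess_plan <- function(x, ...) {
  cat(sprintf("<preprocess_plan> steps: %s; retained %d feature(s), dropped %d\n",
              paste(x$steps, collapse = " -> "), length(x$retained),
              nrow(x$dropped)))
  invisible(x)
}

# Greedy correlated-feature removal on a complete numeric matrix.
# While any off-diagonal |r| > threshold remains: take the worst pair
# (largest |r|), drop its member with the larger mean absolute correlation
# to all other remaining features; ties drop the later column.
find_correlated_matrix <- function(x, threshold, method = "pearson") {
  p <- ncol(x)
  if (p < 2) return(character())
  r <- suppressWarnings(stats::cor(x, method = method))
  r[!is.finite(r)] <- 0  # constant columns correlate with nothing
  diag(r) <- 0
  r <- abs(r)
  alive <- rep(TRUE, p)
  dropped <- character()
  repeat {
    sub <- r[alive, alive, drop = FALSE]
    if (all(sub <= threshold)) break
    idx_alive <- which(alive)
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- idx_alive[w[1]]; b <- idx_alive[w[2]]
    mean_a <- mean(r[a, alive & seq_len(p) != a])
    mean_b <- mean(r[b, alive & seq_len(p) != b])
    victim <- if (mean_a > mean_b) a else if (mean_b > mean_a) b else max(a, b)
    alive[victim] <- FALSE
    dropped <- c(dropped, colnames(x)[victim])
  }
  dropped
}

#' Identify highly correlated predictors to drop
#'
#' Greedy procedure on the absolute correlation matrix: while any
#' off-diagonal \eqn{|r|} exceeds the threshold, the member of the worst
#' pair with the larger mean absolute correlation to all other remaining
#' features is dropped (ties drop the later column in dataset order).
#'
#' @param dataset an `ml_dataset` with a complete (no missing) grid.
#' @param threshold absolute-correlation cutoff in (0, 1).
#' @param method `"pearson"` or `"spearman"`.
#' @return Character vector of feature names in drop order.
#' @export
find_correlated <- function(dataset, threshold = 0.9,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  assert_that(!anyNA(dataset$values),
              "find_correlated requires a complete grid; impute first")
  find_correlated_matrix(dataset$values, threshold, method)
}
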