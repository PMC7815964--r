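# Algorithm registry: each entry wraps a native binary classifier behind a
# uniform surface -- fit(x, y, params), predict_prob(model, x) returning the
# positive-class probability, an optional native importance, and a small
# default hyperparameter grid (<= 5 candidate values per parameter).
#
# x is always a complete numeric matrix (preprocessing runs upstream);
# y a factor with levels c(negative, positive).

# ---- self-written estimators --------------------------------------------

# Shrinkage diagonal discriminant analysis: Gaussian class-conditionals with
# a diagonal covariance whose per-feature pooled variances are shrunk toward
# their median by lambda. Works for p >> n; the shrinkage target stabilises
# low-variance features the same way a moderated t does.
fit_sdda <- function(x, y, lambda) {
  lev <- levels(y)
  split_idx <- split(seq_along(y), y)
  mu <- vapply(split_idx, function(i) colMeans(x[i, , drop = FALSE]),
               numeric(ncol(x)))
  n1 <- length(split_idx[[1]]); n2 <- length(split_idx[[2]])
  ss <- function(i, m) colSums((x[i, , drop = FALSE] -
                                  matrix(m, length(i), ncol(x), byrow = TRUE))^2)
  pooled <- (ss(split_idx[[1]], mu[, 1]) + ss(split_idx[[2]], mu[, 2])) /
    max(1, n1 + n2 - 2)
  v <- (1 - lambda) * pooled + lambda * stats::median(pooled)
  v <- pmax(v, 1e-8)
  list(levels = lev, mu = mu, v = v,
       log_prior = log(c(n1, n2) / (n1 + n2)))
}

predict_sdda <- function(model, x) {
  ll <- vapply(1:2, function(k) {
    centered <- sweep(x, 2, model$mu[, k], "-")
    -0.5 * rowSums(sweep(centered^2, 2, model$v, "/")) -
      0.5 * sum(log(model$v)) + model$log_prior[k]
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) ll <- matrix(ll, nrow = 1)
  # posterior for the positive class (level 2), computed stably
  1 / (1 + exp(ll[, 1] - ll[, 2]))
}

# k-nearest-neighbour posterior: fraction of the k nearest training samples
# (Euclidean distance, stable index tie-break) in the positive class.
fit_knn <- function(x, y, k) list(x = x, y01 = as.numeric(y) - 1, k = k)

predict_knn <- function(model, x) {
  k <- min(model$k, nrow(model$x))
  tx2 <- rowSums(model$x^2)
  apply(x, 1, function(row) {
    d2 <- tx2 - 2 * drop(model$x %*% row)  # + const; order is what matters
    nn <- order(d2)[seq_len(k)]            # order() breaks ties by index
    mean(model$y01[nn])
  })
}

# Bagged classification trees: B rpart trees on seeded bootstrap resamples,
# probabilities averaged.
fit_treebag <- function(x, y, maxdepth, n_trees = 25L, seed = 1L) {
  df <- data.frame(.y = y, x, check.names = FALSE)
  set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(b) {
    idx <- sample(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(maxdepth = maxdepth,
                                                cp = 0.01, xval = 0))
  })
  list(trees = trees, levels = levels(y))
}

predict_treebag <- function(model, x) {
  df <- as.data.frame(x, check.names = FALSE)
  probs <- vapply(model$trees, function(tr)
    stats::predict(tr, df, type = "prob")[, model$levels[2]],
    numeric(nrow(df)))
  if (nrow(df) == 1L) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

# ---- registry ------------------------------------------------------------

#' The classification-algorithm registry
#'
#' Ten representative algorithms spanning the families used in biomedical
#' tabular work: shrinkage (diagonal) discriminant analysis, penalized
#' logistic regression, linear-kernel SVM, naive Bayes, random forest,
#' k-nearest neighbours, bagged trees, gradient boosting, a single-hidden-
#' layer neural net, and a neural net on PCA-extracted features. Each entry
#' carries a small default hyperparameter grid.
#'
#' @param ids optional subset of algorithm ids to return.
#' @return Named list of algorithm specifications.
#' @export
algorithm_registry <- function(ids = NULL) {
  reg <- list(
    sdda = list(
      label = "shrinkage diagonal discriminant analysis",
      grid = list(lambda = c(0, 0.25, 0.5, 0.75, 1)),
      fit = function(x, y, params, seed) fit_sdda(x, y, params$lambda),
      predict = function(model, x) predict_sdda(model, x),
      importance = function(model, x)
        abs(model$mu[, 2] - model$mu[, 1]) / sqrt(model$v)),
    logreg_glmnet = list(
      label = "penalized logistic regression (elastic net)",
      grid = list(alpha = c(0, 0.5, 1), lambda = c(0.001, 0.01, 0.1)),
      fit = function(x, y, params, seed) {
        # default regularization path; predictions interpolate at s
        m <- glmnet::glmnet(x, y, family = "binomial", alpha = params$alpha,
                            nlambda = 50, standardize = TRUE)
        list(fit = m, s = params$lambda, train_sd = apply(x, 2, stats::sd))
      },
      predict = function(model, x)
        drop(stats::predict(model$fit, x, s = model$s, type = "response")),
      importance = function(model, x) {
        beta <- drop(as.matrix(stats::coef(model$fit, s = model$s)))[-1]
        abs(beta) * model$train_sd  # standardized coefficient magnitude
      }),
    svm_linear = list(
      label = "support vector machine, linear kernel",
      grid = list(cost = c(0.1, 1, 10)),
      fit = function(x, y, params, seed) {
        set.seed(seed)  # Platt-scaling CV inside svm() is randomized
        e1071::svm(x, y, kernel = "linear", cost = params$cost,
                   probability = TRUE, scale = FALSE)
      },
      predict = function(model, x) {
        pr <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
        pr[, model$levels[2]]
      },
      importance = NULL),
    naive_bayes = list(
      label = "naive Bayes",
      grid = list(laplace = 0),
      fit = function(x, y, params, seed)
        e1071::naiveBayes(as.data.frame(x, check.names = FALSE), y,
                          laplace = params$laplace),
      predict = function(model, x)
        stats::predict(model, as.data.frame(x, check.names = FALSE),
                       type = "raw")[, model$levels[2]],
      importance = NULL),
    rf = list(
      label = "random forest",
      grid = list(mtry_factor = c(0.5, 1, 2)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        mtry <- max(1L, min(ncol(x),
                            round(params$mtry_factor * sqrt(ncol(x)))))
        randomForest::randomForest(x, y, ntree = 300L, mtry = mtry,
                                   importance = FALSE)
      },
      predict = function(model, x)
        stats::predict(model, x, type = "prob")[, model$classes[2]],
      importance = function(model, x)
        model$importance[, "MeanDecreaseGini"]),
    knn = list(
      label = "k-nearest neighbours",
      grid = list(k = c(5, 9, 15)),
      fit = function(x, y, params, seed) fit_knn(x, y, params$k),
      predict = function(model, x) predict_knn(model, x),
      importance = NULL),
    treebag = list(
      label = "bagged classification trees",
      grid = list(maxdepth = c(2, 5)),
      fit = function(x, y, params, seed)
        fit_treebag(x, y, params$maxdepth, seed = seed),
      predict = function(model, x) predict_treebag(model, x),
      importance = function(model, x) {
        vi <- numeric(ncol(x)); names(vi) <- colnames(x)
        for (tr in model$trees) {
          v <- tr$variable.importance
          if (!is.null(v)) vi[names(v)] <- vi[names(v)] + v
        }
        vi
      }),
    gbm_xgb = list(
      label = "gradient boosting (trees)",
      grid = list(nrounds = c(50, 150), max_depth = c(2, 3)),
      fit = function(x, y, params, seed)
        xgboost::xgboost(x = x, y = y, nrounds = params$nrounds,
                         max_depth = params$max_depth, learning_rate = 0.1,
                         nthreads = 1L, verbosity = 0,
                         seed = seed %% 2147483647),
      predict = function(model, x) stats::predict(model, x),
      importance = function(model, x) {
        imp <- xgboost::xgb.importance(model = model)
        vi <- numeric(ncol(x)); names(vi) <- colnames(x)
        vi[imp$Feature] <- imp$Gain
        vi
      }),
    nnet = list(
      label = "single-hidden-layer neural network",
      grid = list(size = c(3, 5), decay = c(0.01, 0.1)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        nnet::nnet(x, as.numeric(y) - 1, size = params$size,
                   decay = params$decay, maxit = 200, trace = FALSE,
                   entropy = TRUE, MaxNWts = 100000)
      },
      predict = function(model, x) drop(stats::predict(model, x)),
      importance = NULL),
    pca_nnet = list(
      label = "neural network with PCA feature extraction",
      grid = list(n_components = c(5, 10), decay = c(0.1)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        ncomp <- max(1L, min(params$n_components, ncol(x), nrow(x) - 1L))
        pca <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = ncomp)
        net <- nnet::nnet(pca$x, as.numeric(y) - 1, size = 3,
                          decay = params$decay, maxit = 200, trace = FALSE,
                          entropy = TRUE, MaxNWts = 100000)
        list(pca = pca, net = net)
      },
      predict = function(model, x)
        drop(stats::predict(model$net, stats::predict(model$pca, x))),
      importance = NULL)
  )
  if (is.null(ids)) return(reg)
  bad <- setdiff(ids, names(reg))
  assert_that(length(bad) == 0,
              paste("unknown algorithm id(s):", paste(bad, collapse = ", ")))
  reg[ids]
}

#' Algorithm specification for the experiment harness
#'
#' @param algorithm_id a registry id (see [algorithm_registry()]).
#' @param hyperparameter_grid named list of candidate values; `NULL` uses
#'   the registry default.
#' @param selection_metric metric maximized during tuning (default
#'   `"auroc"`).
#' @return An `algorithm_spec`.
#' @export
algorithm_spec <- function(algorithm_id, hyperparameter_grid = NULL,
                           selection_metric = "auroc") {
  entry <- algorithm_registry(algorithm_id)[[1]]
  grid <- hyperparameter_grid %||% entry$grid
  assert_that(length(grid) > 0 && all(lengths(grid) > 0), "grid is empty")
  assert_that(selection_metric %in% metric_names(),
              sprintf("unknown selection metric '%s'", selection_metric))
  structure(list(algorithm_id = algorithm_id, grid = grid,
                 selection_metric = selection_metric, entry = entry),
            class = "algorithm_spec")
}
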