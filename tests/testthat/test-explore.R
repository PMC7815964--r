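test_that("correlation matrix handles exact linear relations and symmetry", {
  set.seed(1)
  x <- matrix(rnorm(40), 20, 2)
  x <- cbind(x, y_lin = 2 * x[, 1] + 3, y_neg = -x[, 2])
  colnames(x) <- c("a", "b", "ylin", "yneg")
  d <- ml_dataset(x, outcome = rep(c("p", "n"), 10), positive_class = "p")
  cr <- correlation_matrix(d)
  expect_equal(unname(cr$r["a", "ylin"]), 1)
  expect_equal(unname(cr$r["b", "yneg"]), -1)
  expect_identical(cr$r, t(cr$r))
  expect_true(all(diag(cr$r) == 1))
  expect_true(all(c("a", "ylin") %in%
                    unlist(cr$high_pairs[1, c("feature_a", "feature_b")])))
})

test_that("pairwise-complete correlations match a per-pair two-pass oracle", {
  set.seed(2)
  v <- matrix(rnorm(100), 20, 5)
  v[matrix(runif(100) < 0.1, 20, 5)] <- NA
  d <- ml_dataset(v, outcome = rep(c("p", "n"), 10), positive_class = "p")
  cr <- correlation_matrix(d, min_pairs = 2)
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !is.na(v[, i]) & !is.na(v[, j])
    a <- v[ok, i]; b <- v[ok, j]
    # two-pass oracle
    r_ref <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(unname(cr$r[i, j]), r_ref, tolerance = 1e-12)
    expect_equal(unname(cr$n_used[i, j]), sum(ok))
  }
})

test_that("constant features are flagged undefined, not zero", {
  v <- cbind(const = rep(3, 10), x = rnorm(10))
  d <- ml_dataset(v, outcome = rep(c("p", "n"), 5), positive_class = "p")
  cr <- correlation_matrix(d)
  expect_true(all(is.na(cr$r["const", ])))
  expect_equal(cr$constant_features, "const")
})

test_that("clustering merges the nearest pair first and recovers blobs", {
  v <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("p0", "p1", "p10"), "x"))
  d <- ml_dataset(v, outcome = c("a", "b", "a"), positive_class = "a")
  hc <- hierarchical_cluster(d, "euclidean", "average")
  expect_equal(hc$height[1], 1)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("p0", "p1"))

  set.seed(3)
  blob <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  labels <- rep(c("lo", "hi"), each = 30)
  d2 <- ml_dataset(blob, outcome = labels, positive_class = "hi")
  hc2 <- hierarchical_cluster(d2)
  groups <- cut_clusters(hc2, 2)
  expect_equal(length(unique(groups[labels == "lo"])), 1L)
  expect_equal(length(unique(groups[labels == "hi"])), 1L)
  expect_false(groups[1] == groups[31])

  # monotone merge heights for average linkage
  expect_true(all(diff(hc2$height) >= -1e-12))

  d_na <- d2; d_na$values[1, 1] <- NA
  expect_error(hierarchical_cluster(d_na), "impute")
})

test_that("clustering is invariant to feature order", {
  set.seed(4)
  v <- matrix(rnorm(80), 16, 5)
  d <- ml_dataset(v, outcome = rep(c("p", "n"), 8), positive_class = "p")
  h1 <- hierarchical_cluster(d)
  d2 <- ml_dataset(v[, 5:1], outcome = rep(c("p", "n"), 8),
                   positive_class = "p")
  h2 <- hierarchical_cluster(d2)
  expect_identical(h1$merge, h2$merge)
  expect_equal(h1$height, h2$height)
})

sam_fixture <- function(n = 20, p = 100, shift_idx = integer(), shift = 0,
                        seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p)
  outcome <- rep(c("control", "case"), each = n / 2)
  x[outcome == "case", shift_idx] <- x[outcome == "case", shift_idx] + shift
  ml_dataset(x, outcome = outcome, positive_class = "case")
}

test_that("SAM d-statistic: zero-difference features and sign-flip symmetry", {
  d <- sam_fixture(seed = 5)
  x <- d$values
  x[, 1] <- rep(c(1, 2, 3, 4, 5), 4)  # identical distribution in both classes
  x[d$outcome == "case", 1] <- x[d$outcome == "control", 1]
  d$values <- x
  sam <- sam_test(d, n_permutations = 25, seed = 1)
  expect_equal(sam$features$d[1], 0, tolerance = 1e-12)

  flipped <- ml_dataset(d$values, outcome = as.character(d$outcome),
                        positive_class = "control",
                        sample_ids = d$sample_ids)
  sam_f <- sam_test(flipped, n_permutations = 25, seed = 1)
  expect_equal(sam_f$features$d, -sam$features$d, tolerance = 1e-12)
})

test_that("SAM called sets shrink monotonically with delta", {
  d <- sam_fixture(shift_idx = 1:10, shift = 2, seed = 6)
  sam <- sam_test(d, n_permutations = 50, seed = 2)
  deltas <- sam$delta_table$delta
  prev <- sam_called(sam, deltas[1])
  for (delta in deltas[-1]) {
    cur <- sam_called(sam, delta)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("SAM permutation null is bit-reproducible given the seed", {
  d <- sam_fixture(shift_idx = 1:5, shift = 1.5, seed = 7)
  s1 <- sam_test(d, n_permutations = 40, seed = 3)
  s2 <- sam_test(d, n_permutations = 40, seed = 3)
  expect_identical(s1$expected, s2$expected)
  expect_identical(s1$delta_table, s2$delta_table)
})

test_that("SAM separates shifted features from a null background", {
  d <- sam_fixture(n = 20, p = 200, shift_idx = 1:20, shift = 2, seed = 8)
  sam <- sam_test(d, n_permutations = 100, seed = 4)
  tab <- sam$delta_table
  usable <- tab[!is.na(tab$fdr) & tab$called >= 10 & tab$called <= 30, ]
  expect_gt(nrow(usable), 0)
  best <- usable[which.min(usable$fdr), ]
  called <- sam_called(sam, best$delta)
  truth <- sprintf("f%d", 1:20)
  # the called set is dominated by genuinely shifted features
  expect_gte(mean(called %in% colnames(d$values)[1:20]), 0.8)
  expect_lte(best$fdr, 0.2)
})

test_that("SAM enumerates all balanced assignments when few exist", {
  d <- sam_fixture(n = 6, p = 30, seed = 9)
  sam <- sam_test(d, n_permutations = 100, seed = 1)
  expect_true(sam$exhaustive)
  expect_equal(sam$n_permutations, choose(6, 3))
  expect_error(sam_test(subset_dataset_for_test(d, 2:5), n_permutations = 10),
               NA)  # 2 per class is the minimum
})
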