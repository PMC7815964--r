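test_that("a complete matrix yields one signature and one resample", {
  d <- complete_toy(n = 6, p = 4)
  sigs <- compute_signatures(d)
  expect_length(sigs, 1L)
  expect_setequal(sigs[[1]]$sample_ids, d$sample_ids)
  rs <- generate_resamples(sigs, min_samples = 1, min_features = 1)
  expect_length(rs, 1L)
  expect_setequal(rs[[1]]$feature_set, d$feature_names)
  expect_setequal(rs[[1]]$sample_ids, d$sample_ids)
})

test_that("the two-block toy yields 2 signatures and the 3 known resamples", {
  d <- toy_two_block()
  sigs <- compute_signatures(d)
  expect_length(sigs, 2L)
  rs <- generate_resamples(sigs, min_samples = 1, min_features = 1)
  expect_length(rs, 3L)
  key <- vapply(rs, function(r) paste(r$feature_set, collapse = ","), "")
  expect_setequal(key, c("f1,f2", "f2,f3", "f2"))
  f2_only <- rs[[which(key == "f2")]]
  expect_setequal(f2_only$sample_ids, c("A", "B", "C", "D"))
  # canonical order: descending n_samples first
  expect_equal(vapply(rs, `[[`, 0L, "n_samples"), c(4L, 2L, 2L))
})

test_that("signatures partition the samples under random missingness", {
  for (seed in 1:5) {
    d <- random_missing_dataset(10, 6, 0.3, seed)
    observed <- d$sample_ids[rowSums(!is.na(d$values)) > 0]
    sigs <- suppressWarnings(compute_signatures(d))
    all_ids <- unlist(lapply(sigs, `[[`, "sample_ids"))
    expect_equal(sort(all_ids), sort(observed))
    expect_false(anyDuplicated(all_ids) > 0)
  }
})

test_that("closure equals brute-force subset enumeration on random inputs", {
  for (seed in 1:20) {
    d <- random_missing_dataset(12, 8, 0.35, seed + 100)
    sigs <- suppressWarnings(compute_signatures(d))
    rs <- generate_resamples(sigs, min_samples = 1, min_features = 1)
    got <- sort(vapply(rs, function(r)
      feature_set_to_mask(r$feature_set, d$feature_names), 0L))
    masks <- vapply(sigs, function(s)
      feature_set_to_mask(s$observed_features, d$feature_names), 0L)
    expect_equal(got, oracle_closure_masks(masks))
  }
})

test_that("closure family is intersection-closed and resamples are maximal", {
  d <- random_missing_dataset(15, 7, 0.3, 9)
  sigs <- suppressWarnings(compute_signatures(d))
  rs <- generate_resamples(sigs, min_samples = 1, min_features = 1)
  fams <- lapply(rs, `[[`, "feature_set")
  keys <- vapply(fams, function(f) paste(sort(f), collapse = ","), "")
  for (i in seq_along(fams)) for (j in seq_len(i - 1)) {
    inter <- intersect(fams[[i]], fams[[j]])
    if (length(inter))
      expect_true(paste(sort(inter), collapse = ",") %in% keys)
  }
  obs <- !is.na(d$values)
  for (r in rs) {
    outside <- setdiff(d$sample_ids, r$sample_ids)
    for (s in outside)
      expect_false(all(obs[s, r$feature_set]))
  }
})

test_that("resample content and order are invariant to row/column shuffling", {
  d <- random_missing_dataset(12, 6, 0.3, 4)
  set.seed(99)
  rp <- sample(nrow(d$values)); cp <- sample(ncol(d$values))
  shuffled <- ml_dataset(d$values[rp, cp, drop = FALSE],
                         outcome = as.character(d$outcome)[rp],
                         positive_class = "case")
  rs1 <- generate_resamples(suppressWarnings(compute_signatures(d)),
                            min_samples = 1, min_features = 1)
  rs2 <- generate_resamples(suppressWarnings(compute_signatures(shuffled)),
                            min_samples = 1, min_features = 1)
  expect_equal(vapply(rs1, `[[`, "", "resample_id"),
               vapply(rs2, `[[`, "", "resample_id"))
  expect_equal(lapply(rs1, `[[`, "feature_set"),
               lapply(rs2, `[[`, "feature_set"))
})

test_that("adding a sample never removes a feature set from the closure", {
  d <- random_missing_dataset(10, 6, 0.3, 11)
  base_ids <- function(dd) vapply(
    generate_resamples(suppressWarnings(compute_signatures(dd)),
                       min_samples = 1, min_features = 1), `[[`, "", "resample_id")
  before <- base_ids(subset_dataset_for_test(d, 1:9))
  after <- base_ids(d)
  expect_true(all(before %in% after))
})

test_that("filter_resamples keeps exactly floor(n * fraction) >= minimum", {
  mk <- function(n) structure(list(feature_set = c("a", "b"),
                                   sample_ids = as.character(seq_len(n)),
                                   n_samples = n, n_features = 2L,
                                   resample_id = sprintf("r%03d", n)),
                              class = "ml_resample")
  rs <- lapply(10:100, mk)
  kept <- filter_resamples(rs, test_fraction = 0.25, min_test_samples = 10)
  expect_equal(vapply(kept, `[[`, 0L, "n_samples"), 40:100)
  expect_length(filter_resamples(list(mk(47)), 0.25, 10), 1L)
  expect_length(filter_resamples(list(mk(39)), 0.25, 10), 0L)
})

test_that("extract_submatrix returns complete grids with canonical order", {
  d <- toy_two_block()
  rs <- generate_resamples(compute_signatures(d), min_samples = 1,
                           min_features = 1)
  shapes <- sort(vapply(rs, function(r) {
    sub <- extract_submatrix(d, r)
    expect_equal(sum(is.na(sub$values)), 0L)
    paste(dim(sub), collapse = "x")
  }, ""))
  expect_equal(shapes, sort(c("2x2", "2x2", "4x1")))
  stale <- rs[[1]]
  stale$sample_ids <- c(stale$sample_ids, "ghost")
  expect_error(extract_submatrix(d, stale), "stale")
})

test_that("samples with zero observed features are excluded with a warning", {
  v <- matrix(c(1, 2, NA, NA, 3, 4), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  d <- ml_dataset(v, outcome = c("x", "y", "x"), positive_class = "x")
  expect_warning(sigs <- compute_signatures(d), "zero observed")
  expect_setequal(unlist(lapply(sigs, `[[`, "sample_ids")), c("a", "c"))
})
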