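# Seeded generators for the dataset archetypes common in biomedical tabular
# work: clinical tables, block-missing multi-assay panels, wide p >> n
# grids, and unbalanced two-class tables. Every pipeline stage is testable
# against these without any download.

#' Specification for a synthetic classification dataset
#'
#' @param n_samples,n_features table shape.
#' @param n_informative number of features carrying a class signal.
#' @param effect_size standardized mean difference (positive minus negative
#'   class) of each informative feature; all features have unit variance.
#' @param class_balance proportion of samples in the positive class.
#' @param missingness `NULL` (complete), or a list of blocks, each
#'   `list(features = <names or indices>, fraction = <sample fraction>)`.
#' @param correlation_structure optional list of
#'   `list(a = <feature>, b = <feature>, r = <target correlation>)` pairs.
#' @param seed integer; identical spec + seed gives a bit-identical dataset.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_samples, n_features, n_informative = 0L,
                       effect_size = 0, class_balance = 0.5,
                       missingness = NULL, correlation_structure = NULL,
                       seed = 1L) {
  assert_that(n_informative <= n_features,
              "n_informative cannot exceed n_features")
  assert_that(class_balance > 0 && class_balance < 1,
              "class_balance must be in (0, 1)")
  n_pos <- round(n_samples * class_balance)
  assert_that(n_pos >= 1 && n_pos <= n_samples - 1,
              "class_balance leaves a class with 0 samples")
  if (!is.null(missingness))
    for (b in missingness)
      assert_that(b$fraction >= 0 && b$fraction <= 1,
                  "block sample fraction must be in [0, 1]")
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, class_balance = class_balance,
                 missingness = missingness,
                 correlation_structure = correlation_structure,
                 seed = as.integer(seed)), class = "synth_spec")
}

#' Generate a two-class Gaussian classification dataset
#'
#' Class-conditional Gaussians with equal (identity) covariance:
#' informative features get a between-class mean shift of `effect_size`
#' (unit variance throughout), so single-feature discrimination has the
#' closed-form AUROC \eqn{\Phi(\mathrm{effect}/\sqrt{2})}. Noise features
#' are standard normal. The ground-truth informative feature names are
#' recorded in the `truth` attribute (and in the sidecar file written by
#' the CLI), never inferred from generator internals by tests.
#'
#' @param spec a [synth_spec()].
#' @return An `ml_dataset` with outcome levels `control`/`case` (positive
#'   `"case"`) and attribute `truth` listing informative features.
#' @export
make_classification_data <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_samples; p <- spec$n_features
  n_pos <- round(n * spec$class_balance)
  outcome <- rep(c("control", "case"), c(n - n_pos, n_pos))
  outcome <- outcome[sample(n)]  # shuffle class layout
  x <- matrix(stats::rnorm(n * p), n, p)
  feature_names <- sprintf("f%03d", seq_len(p))
  colnames(x) <- feature_names
  informative <- feature_names[seq_len(spec$n_informative)]
  if (spec$n_informative > 0)
    x[outcome == "case", informative] <-
      x[outcome == "case", informative] + spec$effect_size
  for (pair in spec$correlation_structure) {
    a <- pair$a; b <- pair$b; r <- pair$r
    x[, b] <- r * x[, a] + sqrt(1 - r^2) * stats::rnorm(n)
  }
  d <- ml_dataset(x, outcome = outcome, positive_class = "case",
                  sample_ids = sprintf("s%04d", seq_len(n)))
  if (!is.null(spec$missingness))
    d <- inject_block_missingness(d, spec$missingness,
                                  seed = derive_seed(spec$seed, "missing"))
  attr(d, "truth") <- informative
  d
}

#' Blank out feature blocks for random sample subsets
#'
#' Emulates multi-assay tables where whole panels are unmeasured for some
#' donors: each block's features are set missing for a seeded random subset
#' of `round(fraction * n)` samples. Blocks are sampled independently, so
#' overlapping subsets realize up to `2^n_blocks` missingness signatures.
#'
#' @param dataset an `ml_dataset`.
#' @param blocks list of `list(features, fraction)`.
#' @param seed integer seed.
#' @return The dataset with missing cells; attribute `missing_rate` records
#'   the realized overall missing-cell proportion.
#' @export
inject_block_missingness <- function(dataset, blocks, seed = 1L) {
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    assert_that(b$fraction >= 0 && b$fraction <= 1,
                "block sample fraction must be in [0, 1]")
    feats <- if (is.numeric(b$features)) dataset$feature_names[b$features]
             else b$features
    unknown <- setdiff(feats, dataset$feature_names)
    assert_that(length(unknown) == 0,
                paste("block references unknown feature(s):",
                      paste(unknown, collapse = ", ")))
    set.seed(derive_seed(seed, "block", k))
    hit <- sample(n_samples(dataset), round(b$fraction * n_samples(dataset)))
    dataset$values[hit, feats] <- NA_real_
  }
  attr(dataset, "missing_rate") <- mean(is.na(dataset$values))
  dataset
}

#' Preset archetypes of the case-study dataset shapes
#'
#' Five presets emulating the shapes, prevalences, and missingness rates of
#' typical biomedical case studies:
#' \describe{
#'   \item{`sisa`}{clinical table, 534 x 14, complete, near-balanced.}
#'   \item{`cyclists`}{multi-assay immunophenotyping table, 195 samples x
#'     90 features (120 positive : 75), two feature blocks unmeasured for
#'     subsets of donors giving ~8\% missing cells.}
#'   \item{`vast`}{serology trial table, 72 samples x 60 features (26
#'     positive : 46), two larger blocks giving ~21\% missing cells.}
#'   \item{`zeller`}{wide microbiome-like table, 184 samples x 800 features
#'     (91 positive : 93), complete.}
#'   \item{`lihc`}{unbalanced expression-like table, 424 samples x 300
#'     features at 374 positive : 50 negative, complete.}
#' }
#' All values are synthetic draws from the Gaussian generator; only shape,
#' prevalence, and missingness structure are matched to the archetype.
#'
#' @param name archetype name.
#' @param seed integer seed.
#' @return An `ml_dataset` (attributes `truth`, and `missing_rate` where
#'   missingness is injected).
#' @export
archetype_dataset <- function(name = c("sisa", "cyclists", "vast", "zeller",
                                       "lihc"), seed = 1L) {
  name <- match.arg(name)
  spec <- switch(name,
    sisa = synth_spec(534, 14, n_informative = 3, effect_size = 1,
                      class_balance = 0.5, seed = seed),
    cyclists = synth_spec(195, 90, n_informative = 8, effect_size = 1,
                          class_balance = 120 / 195,
                          missingness = list(
                            list(features = sprintf("f%03d", 61:78),
                                 fraction = 0.20),
                            list(features = sprintf("f%03d", 79:90),
                                 fraction = 0.30)),
                          seed = seed),
    vast = synth_spec(72, 60, n_informative = 6, effect_size = 1,
                      class_balance = 26 / 72,
                      missingness = list(
                        list(features = sprintf("f%03d", 25:44),
                             fraction = 0.35),
                        list(features = sprintf("f%03d", 45:60),
                             fraction = 0.35)),
                      seed = seed),
    zeller = synth_spec(184, 800, n_informative = 20, effect_size = 0.8,
                        class_balance = 91 / 184, seed = seed),
    lihc = synth_spec(424, 300, n_informative = 10, effect_size = 1.5,
                      class_balance = 374 / 424, seed = seed))
  make_classification_data(spec)
}

#' Write the ground-truth sidecar for a generated dataset
#'
#' Kept separate from the data file so generated CSVs are schema-identical
#' to real inputs.
#'
#' @param dataset a generated `ml_dataset` with a `truth` attribute.
#' @param path output path (TSV: one informative feature name per line).
#' @return Invisibly, `path`.
#' @export
write_truth_sidecar <- function(dataset, path) {
  truth <- attr(dataset, "truth") %||% character()
  writeLines(c("informative_feature", truth), path)
  invisible(path)
}

#' Read a ground-truth sidecar
#' @param path sidecar path.
#' @return Character vector of informative feature names.
#' @export
read_truth_sidecar <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 1 && lines[1] == "informative_feature",
              "not a truth sidecar file")
  lines[-1]
}
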