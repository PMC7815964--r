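# Multiset intersection resampling: turn a table with missing cells into the
# family of all complete submatrices ("resamples") obtainable by intersecting
# per-sample observed-feature signatures.

#' Group samples by their observed-feature signature
#'
#' A sample's signature is the set of features with a non-missing cell.
#' Samples sharing a signature form one group; the groups partition the
#' sample set. Samples observing zero features are excluded with a warning.
#'
#' @param dataset an `ml_dataset`.
#' @return A list of signatures, each `list(observed_features, sample_ids)`,
#'   sorted by descending group size, ties by the lexicographic order of the
#'   sorted feature set.
#' @export
compute_signatures <- function(dataset) {
  assert_that(n_samples(dataset) >= 1, "dataset has no samples")
  obs <- !is.na(dataset$values)
  empty <- rowSums(obs) == 0
  if (any(empty)) {
    warning(sprintf("excluding %d sample(s) with zero observed features: %s",
                    sum(empty),
                    paste(dataset$sample_ids[empty], collapse = ", ")))
    obs <- obs[!empty, , drop = FALSE]
  }
  ids <- rownames(obs)
  keys <- apply(obs, 1, function(r)
    paste(sort(dataset$feature_names[r]), collapse = "\n"))
  groups <- split(ids, keys)
  sigs <- lapply(names(groups), function(k) {
    list(observed_features = strsplit(k, "\n", fixed = TRUE)[[1]],
         sample_ids = groups[[k]])
  })
  ord <- order(-lengths(lapply(sigs, `[[`, "sample_ids")),
               vapply(sigs, function(s)
                 paste(s$observed_features, collapse = "\n"), ""))
  sigs[ord]
}

new_resample <- function(feature_set, sample_ids) {
  feature_set <- sort(feature_set)
  structure(list(feature_set = feature_set,
                 sample_ids = sample_ids,
                 n_samples = length(sample_ids),
                 n_features = length(feature_set),
                 resample_id = stable_digest(paste(feature_set, collapse = "\n"))),
            class = "ml_resample")
}

#' @export
print.ml_resample <- function(x, ...) {
  cat(sprintf("<resample %s> %d samples x %d features\n",
              substr(x$resample_id, 1, 8), x$n_samples, x$n_features))
  invisible(x)
}

#' Generate all complete-submatrix resamples from signatures
#'
#' Computes the intersection closure of the signature feature sets — every
#' distinct non-empty intersection over every non-empty subset of signatures
#' — by iterated pairwise intersection to a fixed point with hash
#' deduplication. Each emitted feature set is paired with the maximal sample
#' set observing all of it. Resamples smaller than the configured minima are
#' dropped after the closure is complete.
#'
#' @param signatures output of [compute_signatures()].
#' @param min_samples,min_features minimum resample size kept (defaults 15
#'   and 2: below that, 10-fold cross-validation folds degenerate).
#' @param max_sets cap on distinct feature sets in the closure; exceeding it
#'   raises a resource error (the missingness pattern is too fragmented and
#'   should be coarsened into assay blocks).
#' @return A list of `ml_resample`, sorted by descending `n_samples`, then
#'   descending `n_features`, then `resample_id`.
#' @export
generate_resamples <- function(signatures, min_samples = 15L,
                               min_features = 2L, max_sets = 10000L) {
  assert_that(length(signatures) >= 1, "need at least one signature")
  seen <- new.env(parent = emptyenv())
  fam <- list()
  add_set <- function(feats) {
    key <- paste(feats, collapse = "\n")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      fam[[length(fam) + 1L]] <<- feats
      if (length(fam) > max_sets)
        stop(sprintf(paste("resample closure exceeds %d feature sets;",
                           "coarsen the missingness pattern into assay blocks"),
             max_sets), call. = FALSE)
      TRUE
    } else FALSE
  }
  for (s in signatures) add_set(sort(s$observed_features))

  # worklist closure: intersect each pending set against every known set;
  # new non-empty intersections join both the family and the worklist
  pending <- 1L
  while (pending <= length(fam)) {
    cur <- fam[[pending]]
    n_known <- length(fam)
    for (j in seq_len(n_known)) {
      if (j == pending) next
      inter <- intersect(cur, fam[[j]])
      if (length(inter)) add_set(sort(inter))
    }
    pending <- pending + 1L
  }

  sig_feats <- lapply(signatures, `[[`, "observed_features")
  sig_ids <- lapply(signatures, `[[`, "sample_ids")
  out <- lapply(fam, function(feats) {
    covered <- vapply(sig_feats, function(sf) all(feats %in% sf), NA)
    new_resample(feats, sort(unlist(sig_ids[covered], use.names = FALSE)))
  })
  out <- Filter(function(r) r$n_samples >= min_samples &&
                  r$n_features >= min_features, out)
  ord <- order(-vapply(out, `[[`, 0L, "n_samples"),
               -vapply(out, `[[`, 0L, "n_features"),
               vapply(out, `[[`, "", "resample_id"))
  out[ord]
}

#' Filter resamples by the size of their prospective test split
#'
#' Keeps resamples whose holdout split would contain at least
#' `min_test_samples` samples, i.e. `floor(n_samples * test_fraction) >=
#' min_test_samples`, to prevent overly optimistic estimates from tiny
#' holdout sets.
#'
#' @param resamples list of `ml_resample`.
#' @param test_fraction proportion of samples destined for the holdout split.
#' @param min_test_samples minimum holdout size.
#' @return The kept resamples, input order preserved.
#' @export
filter_resamples <- function(resamples, test_fraction = 0.25,
                             min_test_samples = 10L) {
  assert_that(test_fraction > 0 && test_fraction < 1,
              "test_fraction must be in (0, 1)")
  keep <- vapply(resamples, function(r)
    floor(r$n_samples * test_fraction) >= min_test_samples, NA)
  resamples[keep]
}

#' Extract the complete submatrix a resample describes
#'
#' @param dataset the `ml_dataset` the resample was derived from.
#' @param resample an `ml_resample`.
#' @return An `ml_dataset` with zero missing cells; rows and columns are
#'   restricted to the resample and kept in the parent dataset's order.
#' @export
extract_submatrix <- function(dataset, resample) {
  missing_s <- setdiff(resample$sample_ids, dataset$sample_ids)
  missing_f <- setdiff(resample$feature_set, dataset$feature_names)
  assert_that(length(missing_s) == 0 && length(missing_f) == 0,
              "stale resample: sample or feature absent from dataset")
  si <- dataset$sample_ids[dataset$sample_ids %in% resample$sample_ids]
  fi <- dataset$feature_names[dataset$feature_names %in% resample$feature_set]
  out <- subset_dataset(dataset, samples = si, features = fi)
  assert_that(!anyNA(out$values),
              "resample does not describe a complete submatrix of this dataset")
  out
}

#' Resample manifest as a data.frame
#' @param resamples list of `ml_resample`.
#' @return data.frame with one row per resample.
#' @export
resample_manifest <- function(resamples) {
  data.frame(
    resample_id = vapply(resamples, `[[`, "", "resample_id"),
    n_samples = vapply(resamples, `[[`, 0L, "n_samples"),
    n_features = vapply(resamples, `[[`, 0L, "n_features"),
    features = vapply(resamples, function(r)
      paste(r$feature_set, collapse = ";"), ""),
    samples = vapply(resamples, function(r)
      paste(r$sample_ids, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
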