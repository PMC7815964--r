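# Dataset container and delimited-table I/O with an explicit modelling schema.

#' Construct a modelling dataset
#'
#' The central container of the package: a samples x features numeric grid
#' (missing cells as `NA`), a two-class outcome with a designated positive
#' class, and optional "exploration" columns that are excluded from the
#' predictors but kept for exploratory analysis.
#'
#' @param values numeric matrix, rows = samples, columns = features. Row and
#'   column names are used as sample ids / feature names if `sample_ids` or
#'   `feature_names` are not given.
#' @param outcome vector of per-sample class labels with exactly two observed
#'   levels; no missing values allowed.
#' @param positive_class the outcome level treated as the positive class.
#' @param sample_ids,feature_names optional explicit identifiers.
#' @param exploration optional data.frame of exploration columns (same row
#'   count as `values`).
#' @param outcome_name,id_name column names used when the dataset is written
#'   back to disk.
#' @return An object of class `ml_dataset`.
#' @export
ml_dataset <- function(values, outcome, positive_class,
                       sample_ids = rownames(values),
                       feature_names = colnames(values),
                       exploration = NULL,
                       outcome_name = "outcome", id_name = "sample_id") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(values)))
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  assert_that(length(sample_ids) == nrow(values),
              "sample_ids length must equal the grid row count")
  assert_that(length(feature_names) == ncol(values),
              "feature_names length must equal the grid column count")
  assert_that(!anyDuplicated(sample_ids), "duplicate sample ids")
  assert_that(!anyDuplicated(feature_names), "duplicate feature names")
  assert_that(!anyNA(outcome), "outcome must be defined for every sample")
  assert_that(length(outcome) == nrow(values),
              "outcome length must equal the sample count")
  lev <- unique(as.character(outcome))
  assert_that(length(lev) == 2L,
              sprintf("outcome must have exactly 2 observed levels, found %d",
                      length(lev)))
  assert_that(positive_class %in% lev,
              sprintf("positive class '%s' not among outcome levels", positive_class))
  negative <- setdiff(lev, positive_class)
  outcome <- factor(as.character(outcome), levels = c(negative, positive_class))
  if (!is.null(exploration)) {
    exploration <- as.data.frame(exploration, stringsAsFactors = FALSE)
    assert_that(nrow(exploration) == nrow(values),
                "exploration rows must match the sample count")
    assert_that(!any(colnames(exploration) %in% feature_names),
                "exploration columns must be disjoint from predictors")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(list(values = values, outcome = outcome,
                 positive_class = positive_class,
                 sample_ids = sample_ids, feature_names = feature_names,
                 exploration = exploration,
                 outcome_name = outcome_name, id_name = id_name),
            class = "ml_dataset")
}

#' @export
print.ml_dataset <- function(x, ...) {
  nm <- sum(is.na(x$values))
  cat(sprintf("<ml_dataset> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  outcome '%s': %s (positive: %s)\n", x$outcome_name,
              paste(sprintf("%s=%d", levels(x$outcome), table(x$outcome)),
                    collapse = ", "), x$positive_class))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm,
              100 * nm / max(1, length(x$values))))
  if (!is.null(x$exploration))
    cat(sprintf("  exploration columns: %s\n",
                paste(colnames(x$exploration), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ml_dataset <- function(x) dim(x$values)

#' Number of samples / features in a dataset
#' @param dataset an `ml_dataset`.
#' @return integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_features <- function(dataset) ncol(dataset$values)

#' Fraction of missing predictor cells
#' @param dataset an `ml_dataset`.
#' @return proportion in \[0, 1\].
#' @export
missing_rate <- function(dataset) mean(is.na(dataset$values))

# Subset rows/columns preserving dataset order; idx are sample ids / feature
# names or logical/integer indices.
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(dataset)) else samples
  fi <- if (is.null(features)) seq_len(n_features(dataset)) else features
  if (is.character(si)) si <- match(si, dataset$sample_ids)
  if (is.character(fi)) fi <- match(fi, dataset$feature_names)
  assert_that(!anyNA(si), "unknown sample id")
  assert_that(!anyNA(fi), "unknown feature name")
  ml_dataset(dataset$values[si, fi, drop = FALSE],
             outcome = as.character(dataset$outcome)[si],
             positive_class = dataset$positive_class,
             sample_ids = dataset$sample_ids[si],
             feature_names = dataset$feature_names[fi],
             exploration = if (!is.null(dataset$exploration))
               dataset$exploration[si, , drop = FALSE],
             outcome_name = dataset$outcome_name, id_name = dataset$id_name)
}

#' Describe how a delimited file maps onto the modelling schema
#'
#' @param outcome_column name of the outcome column in the file header.
#' @param positive_class outcome level to treat as positive.
#' @param id_column name of the sample-identifier column, or `NULL` to number
#'   samples by row.
#' @param exploration_columns columns excluded from the predictors but kept
#'   for exploratory analysis.
#' @param missing_markers string tokens treated as missing cells
#'   (case-insensitive).
#' @param delimiter `","`, `"\t"` or `NULL` to auto-detect from the header.
#' @return A `schema_spec` list.
#' @export
schema_spec <- function(outcome_column, positive_class, id_column = NULL,
                        exploration_columns = character(),
                        missing_markers = c("", "NA", "NaN", "null"),
                        delimiter = NULL) {
  structure(list(outcome_column = outcome_column,
                 positive_class = positive_class,
                 id_column = id_column,
                 exploration_columns = as.character(exploration_columns),
                 missing_markers = tolower(missing_markers),
                 delimiter = delimiter),
            class = "schema_spec")
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE)))
  n_com <- lengths(regmatches(header, gregexpr(",", header, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0) "\t" else ","
}

#' Read a delimited feature table into an `ml_dataset`
#'
#' Reads a CSV/TSV with one header row, validates it against the schema and
#' parses predictor columns as numeric. Cells matching a missing marker
#' (case-insensitive) become `NA`; any other non-numeric token in a
#' predictor column is an error naming the offending row and column.
#'
#' @param path file path.
#' @param schema a [schema_spec()].
#' @return An `ml_dataset`.
#' @export
read_dataset <- function(path, schema) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  sep <- schema$delimiter %||% detect_delimiter(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character(),
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  hdr <- colnames(raw)
  if (anyDuplicated(hdr))
    stop("schema error: duplicate header names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "), call. = FALSE)
  assert_that(schema$outcome_column %in% hdr,
              sprintf("schema error: outcome column '%s' not in header",
                      schema$outcome_column))
  missing_cols <- setdiff(schema$exploration_columns, hdr)
  assert_that(length(missing_cols) == 0,
              paste("schema error: exploration columns not in header:",
                    paste(missing_cols, collapse = ", ")))

  sample_ids <- if (!is.null(schema$id_column)) {
    assert_that(schema$id_column %in% hdr,
                sprintf("schema error: id column '%s' not in header", schema$id_column))
    raw[[schema$id_column]]
  } else as.character(seq_len(nrow(raw)))

  outcome <- raw[[schema$outcome_column]]
  lev <- unique(outcome[!is.na(outcome) & outcome != ""])
  if (length(lev) != 2L)
    stop(sprintf("schema error: outcome has %d observed levels, need exactly 2",
                 length(lev)), call. = FALSE)
  assert_that(schema$positive_class %in% lev,
              sprintf("schema error: positive class '%s' not observed in outcome",
                      schema$positive_class))

  pred_cols <- setdiff(hdr, c(schema$outcome_column, schema$id_column,
                              schema$exploration_columns))
  vals <- matrix(NA_real_, nrow(raw), length(pred_cols),
                 dimnames = list(sample_ids, pred_cols))
  for (j in seq_along(pred_cols)) {
    tok <- trimws(raw[[pred_cols[j]]])
    is_missing <- tolower(tok) %in% schema$missing_markers
    num <- suppressWarnings(as.numeric(tok))
    bad <- !is_missing & (is.na(num) | !is.finite(num))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("parse error: non-numeric value '%s' at row %d, column '%s'",
                   tok[i], i, pred_cols[j]), call. = FALSE)
    }
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }

  exploration <- if (length(schema$exploration_columns))
    raw[, schema$exploration_columns, drop = FALSE]
  ml_dataset(vals, outcome = outcome, positive_class = schema$positive_class,
             sample_ids = sample_ids, feature_names = pred_cols,
             exploration = exploration,
             outcome_name = schema$outcome_column,
             id_name = schema$id_column %||% "sample_id")
}

#' Write an `ml_dataset` back to a delimited file
#'
#' Emits a single header row and one row per sample: the id column, every
#' predictor column in stored order, the outcome column, and any exploration
#' columns. Missing cells are written as `missing_marker`.
#'
#' @param dataset an `ml_dataset`.
#' @param path output path; `.tsv`/`.txt` extensions switch to tab delimiter.
#' @param missing_marker token used for missing cells (default `"NA"`).
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, missing_marker = "NA") {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- data.frame(id = dataset$sample_ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  colnames(df) <- dataset$id_name
  vals <- dataset$values
  for (j in seq_len(ncol(vals))) {
    col <- format(vals[, j], trim = TRUE, digits = 15, scientific = NA)
    col[is.na(vals[, j])] <- missing_marker
    df[[dataset$feature_names[j]]] <- col
  }
  df[[dataset$outcome_name]] <- as.character(dataset$outcome)
  if (!is.null(dataset$exploration))
    for (nm in colnames(dataset$exploration))
      df[[nm]] <- dataset$exploration[[nm]]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop named columns, then samples that still have missing predictor cells
#'
#' Mirrors the usual clinical-table cleanup: columns known to be sparsely
#' measured are removed first; any sample still carrying a missing predictor
#' cell afterwards is removed.
#'
#' @param dataset an `ml_dataset`.
#' @param drop_columns feature names to remove before the row filter.
#' @return A list with `dataset` (the filtered `ml_dataset`) and
#'   `removed_samples` (ids removed by the row filter).
#' @export
drop_incomplete <- function(dataset, drop_columns = character()) {
  unknown <- setdiff(drop_columns, dataset$feature_names)
  assert_that(length(unknown) == 0,
              paste("unknown column name(s):", paste(unknown, collapse = ", ")))
  keep_f <- setdiff(dataset$feature_names, drop_columns)
  d <- subset_dataset(dataset, features = keep_f)
  complete <- rowSums(is.na(d$values)) == 0
  removed <- d$sample_ids[!complete]
  list(dataset = subset_dataset(d, samples = which(complete)),
       removed_samples = removed)
}
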