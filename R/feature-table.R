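#' Read a delimited athlete feature table
#'
#' Reads a delimited text file (CSV by default) into a tidy feature table:
#' a tibble whose first column is `sample_id`, followed by an optional label
#' column (kept as a factor) and numeric feature columns. The file must have
#' a header row; its first column is taken as the sample identifier. Empty
#' cells, `"NA"` and `"NaN"` (case-insensitive) are recorded as missing.
#'
#' @param path Path to the delimited file.
#' @param label_column Optional name of a column holding ground-truth class
#'   labels; it is converted to a factor rather than parsed as a feature.
#' @param delimiter Field separator, `","` by default (use `"\t"` for TSV).
#' @return A tibble with columns `sample_id`, the label column (if any), and
#'   one numeric column per feature. Missing entries are `NA`.
#' @seealso [write_feature_table()], [clean_features()], [standardize_features()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,height,weight", "a,180,75", "b,170,NA"), path)
#' read_feature_table(path)
read_feature_table <- function(path, label_column = NULL, delimiter = ",") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(
    path, delim = delimiter, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, progress = FALSE,
    show_col_types = FALSE
  )
  if (ncol(raw) < 2L) abort("expected a sample-id column plus at least one feature column")
  names(raw)[1] <- "sample_id"
  ids <- raw$sample_id
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf("duplicate sample IDs: %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(label_column)) {
    if (!label_column %in% names(raw)) {
      abort(sprintf("label column '%s' not found in %s", label_column, path))
    }
  }
  feat_names <- setdiff(names(raw), c("sample_id", label_column))
  if (length(feat_names) == 0L) abort("no feature columns remain after removing id/label columns")

  parse_col <- function(x, col) {
    missing_mask <- is.na(x) | x == "" | tolower(x) %in% c("na", "nan")
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!missing_mask & is.na(out))
    if (length(bad) > 0L) {
      abort(sprintf("non-numeric value '%s' in column '%s', row %d",
                    x[bad[1]], col, bad[1]))
    }
    out[missing_mask] <- NA_real_
    out
  }
  out <- tibble::tibble(sample_id = as.character(ids))
  if (!is.null(label_column)) out[[label_column]] <- factor(raw[[label_column]])
  for (col in feat_names) out[[col]] <- parse_col(raw[[col]], col)
  out
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: writes the tibble with a header row,
#' `sample_id` first, using `"NA"` for missing entries. Numeric values are
#' written with round-trip precision.
#'
#' @param data A feature table tibble.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(data, path, delimiter = ",") {
  stopifnot(is.data.frame(data))
  readr::write_delim(data, path, delim = delimiter, na = "NA", progress = FALSE)
  invisible(path)
}

#' Clean a feature table
#'
#' Applies the standard cleaning chain: exact duplicate rows (identical
#' across all feature columns) are dropped keeping the first occurrence,
#' feature columns whose missing fraction exceeds a threshold are dropped,
#' and remaining missing entries are either mean-imputed or their rows
#' removed. A cleaning report is attached as the `"clean_report"` attribute
#' (see [clean_report()]).
#'
#' @param data A feature table tibble (numeric columns are the features).
#' @param duplicate_removal Drop exact duplicate feature rows? Default `TRUE`.
#' @param missing_feature_drop_fraction Columns with a larger fraction of
#'   missing entries are dropped. Default `0.5`.
#' @param imputation Either `"mean"` (impute the column mean of the observed
#'   entries) or `"drop_row"` (remove rows with any missing entry).
#' @return The cleaned tibble, with no missing entries and no duplicate
#'   feature rows, carrying a `"clean_report"` attribute.
#' @export
clean_features <- function(data,
                           duplicate_removal = TRUE,
                           missing_feature_drop_fraction = 0.5,
                           imputation = c("mean", "drop_row")) {
  imputation <- match.arg(imputation)
  stopifnot(is.data.frame(data),
            missing_feature_drop_fraction >= 0, missing_feature_drop_fraction <= 1)
  out <- tibble::as_tibble(data)
  feats <- feature_cols(out)
  if (length(feats) == 0L) abort("no numeric feature columns to clean")

  dup_removed <- 0L
  if (duplicate_removal) {
    dup <- duplicated(out[feats])
    dup_removed <- sum(dup)
    out <- out[!dup, , drop = FALSE]
  }

  miss_frac <- vapply(out[feats], function(x) mean(is.na(x)), numeric(1))
  drop_cols <- feats[miss_frac > missing_feature_drop_fraction]
  if (length(drop_cols) > 0L) out <- out[setdiff(names(out), drop_cols)]
  feats <- setdiff(feats, drop_cols)
  if (length(feats) == 0L) abort("all feature columns were dropped by the missing-fraction threshold")

  rows_dropped <- 0L
  imputed <- 0L
  if (imputation == "drop_row") {
    keep <- !apply(is.na(out[feats]), 1L, any)
    rows_dropped <- sum(!keep)
    out <- out[keep, , drop = FALSE]
  } else {
    for (col in feats) {
      nas <- is.na(out[[col]])
      if (any(nas)) {
        if (all(nas)) abort(sprintf("column '%s' has no observed entries to impute from", col))
        out[[col]][nas] <- mean(out[[col]][!nas])
        imputed <- imputed + sum(nas)
      }
    }
  }
  if (nrow(out) == 0L) abort("all rows were removed during cleaning")

  # imputation can create new exact duplicates; the contract is no duplicates
  if (duplicate_removal) {
    dup <- duplicated(out[feats])
    dup_removed <- dup_removed + sum(dup)
    out <- out[!dup, , drop = FALSE]
  }

  attr(out, "clean_report") <- list(
    duplicates_removed = as.integer(dup_removed),
    columns_dropped = drop_cols,
    rows_dropped = as.integer(rows_dropped),
    entries_imputed = as.integer(imputed)
  )
  out
}

#' Retrieve the cleaning report attached by [clean_features()]
#'
#' @param data A tibble returned by [clean_features()].
#' @return A list with `duplicates_removed`, `columns_dropped`,
#'   `rows_dropped` and `entries_imputed`.
#' @export
clean_report <- function(data) {
  rep <- attr(data, "clean_report")
  if (is.null(rep)) abort("no clean_report attribute; was this produced by clean_features()?")
  rep
}

#' Standardize feature columns to zero mean and unit spread
#'
#' Each numeric column is transformed to `(x - mean) / sd` using the
#' population standard deviation (divisor `n`). Columns with zero spread
#' become all-zeros. Missing entries are an error; clean first.
#'
#' @param data A feature table tibble with no missing entries.
#' @return The tibble with standardized feature columns.
#' @export
standardize_features <- function(data) {
  out <- tibble::as_tibble(data)
  feats <- feature_cols(out)
  check_no_missing(as.matrix(out[feats]), "feature table")
  n <- nrow(out)
  for (col in feats) {
    x <- out[[col]]
    mu <- mean(x)
    sigma <- sqrt(sum((x - mu)^2) / n)
    out[[col]] <- if (sigma > 0) (x - mu) / sigma else rep(0, n)
  }
  out
}

#' Randomly subsample rows of a feature table
#'
#' Draws `n_sub` rows uniformly without replacement, reproducibly from
#' `seed`. Selected rows keep their original relative order, so
#' `n_sub = nrow(data)` returns the table unchanged.
#'
#' @param data A feature table tibble.
#' @param n_sub Number of rows to keep (between 2 and `nrow(data)`).
#' @param seed Integer seed controlling the draw.
#' @return The subsampled tibble.
#' @export
subsample_features <- function(data, n_sub, seed = 1L) {
  n <- nrow(data)
  if (n_sub < 2L || n_sub > n) {
    abort(sprintf("n_sub must be between 2 and %d, got %s", n, n_sub))
  }
  idx <- with_seed(seed_stream(seed, "subsample"), sample.int(n, n_sub))
  data[sort(idx), , drop = FALSE]
}
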