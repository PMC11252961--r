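#' Pairwise distance matrix of a feature table
#'
#' Computes the full symmetric `n x n` distance matrix over the numeric
#' feature columns. Euclidean (the default) and Manhattan delegate to
#' [stats::dist()]; cosine distance is `1 - cos` similarity of the feature
#' vectors.
#'
#' @param data A feature table tibble with no missing entries, or a numeric
#'   matrix.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"cosine"`.
#' @return A symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames where available, and the metric name in the `"metric"`
#'   attribute.
#' @export
feature_distances <- function(data, metric = c("euclidean", "manhattan", "cosine")) {
  metric <- match.arg(metric)
  m <- if (is.matrix(data)) data else feature_matrix(data)
  check_no_missing(m, "feature table")
  if (nrow(m) < 2L) abort("need at least 2 samples")
  if (metric %in% c("euclidean", "manhattan")) {
    d <- as.matrix(stats::dist(m, method = metric))
  } else {
    norms <- sqrt(rowSums(m^2))
    if (any(norms == 0)) abort("cosine distance undefined for all-zero rows")
    sim <- (m %*% t(m)) / outer(norms, norms)
    d <- 1 - pmin(pmax(sim, -1), 1)
    diag(d) <- 0
    d <- (d + t(d)) / 2
    dimnames(d) <- list(rownames(m), rownames(m))
  }
  attr(d, "metric") <- metric
  d
}
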