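#' Write a partition to CSV
#'
#' Two columns, `sample_id` and `cluster`, one row per sample.
#'
#' @param fit An `aco_fit`, or a named integer/factor assignment vector.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(fit, path) {
  labels <- if (inherits(fit, "aco_fit")) fit$labels else fit
  df <- tibble::tibble(
    sample_id = names(labels) %||% as.character(seq_along(labels)),
    cluster = as.integer(labels)
  )
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Serialize a run result to JSON
#'
#' Writes the configuration echo (with its hash), the cluster assignment,
#' best cost, convergence information and per-iteration history.
#'
#' @param fit An `aco_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_json <- function(fit, path) {
  stopifnot(inherits(fit, "aco_fit"))
  payload <- list(
    config = unclass(fit$config),
    config_hash = config_hash(fit$config),
    labels = setNames(as.list(unname(fit$labels)), names(fit$labels)),
    best_cost = fit$best$cost,
    best_iteration = fit$best$iteration,
    converged_at = fit$converged_at,
    iterations_run = fit$iterations_run,
    history = fit$history
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
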