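#' @export
print.aco_fit <- function(x, ...) {
  n <- length(x$labels)
  sizes <- table(x$labels)
  cat(sprintf("<aco_fit> %d samples in %d clusters (sizes %s)\n",
              n, x$config$k, paste(sizes, collapse = "/")))
  cat(sprintf("  best cost %.4f (iteration %d); ran %d iterations%s\n",
              x$best$cost, x$best$iteration, x$iterations_run,
              if (is.na(x$converged_at)) ""
              else sprintf(", converged at %d", x$converged_at)))
  invisible(x)
}

#' Tidy an ant colony clustering fit
#'
#' @param x An `aco_fit` from [aco_cluster()].
#' @param ... Unused.
#' @return A tibble with one row per sample: `sample_id`, `cluster`, and
#'   the sample's silhouette width.
#' @export
tidy.aco_fit <- function(x, ...) {
  out <- tibble::tibble(sample_id = names(x$labels),
                        cluster = unname(x$labels))
  if (x$config$k >= 2L && length(x$labels) >= 3L) {
    out$silhouette <- silhouette_samples(x$dist, x$labels)$silhouette
  }
  out
}

#' One-row summary of an ant colony clustering fit
#'
#' @param x An `aco_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `m`, `iterations_run`,
#'   `converged_at`, `best_cost`, `silhouette`, `davies_bouldin`.
#' @export
glance.aco_fit <- function(x, ...) {
  has_internal <- x$config$k >= 2L && length(x$labels) >= 3L && !is.null(x$data)
  tibble::tibble(
    k = x$config$k,
    n = length(x$labels),
    m = x$config$m,
    iterations_run = x$iterations_run,
    converged_at = x$converged_at,
    best_cost = x$best$cost,
    silhouette = if (x$config$k >= 2L) silhouette_score(x$dist, x$labels) else NA_real_,
    davies_bouldin = if (has_internal) davies_bouldin(x$data, x$labels) else NA_real_
  )
}

#' Augment data with ant colony cluster assignments
#'
#' @param x An `aco_fit` fitted on a data frame.
#' @param data The data to augment; defaults to the training data.
#' @param ... Unused.
#' @return `data` with a `.cluster` factor column appended.
#' @export
augment.aco_fit <- function(x, data = NULL, ...) {
  data <- data %||% x$data
  if (is.null(data)) abort("no data to augment; supply `data`")
  data <- tibble::as_tibble(data)
  stopifnot(nrow(data) == length(x$labels))
  data$.cluster <- factor(unname(x$labels))
  data
}

#' Plot an ant colony clustering fit
#'
#' `type = "clusters"` shows the samples on the first two principal
#' components of the feature space, coloured by cluster; `type = "history"`
#' shows the per-iteration best/mean cost and the pheromone change rate.
#'
#' @param object An `aco_fit`.
#' @param type `"clusters"` or `"history"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aco_fit <- function(object, type = c("clusters", "history"), ...) {
  type <- match.arg(type)
  if (type == "history") {
    long <- object$history |>
      tidyr::pivot_longer(-"iteration", names_to = "series", values_to = "value")
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
        ggplot2::geom_line() +
        ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
        ggplot2::labs(x = "iteration", y = NULL,
                      title = "Ant colony run history") +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(object$data)) abort("fit carries no data; use type = 'history'")
  m <- feature_matrix(object$data)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)$x
  df <- tibble::tibble(PC1 = pc[, 1],
                       PC2 = if (ncol(pc) > 1) pc[, 2] else 0,
                       cluster = factor(unname(object$labels)))
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(title = sprintf("Ant colony clustering (k = %d)", object$config$k)) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-count scan
#'
#' @param object An `aco_scan` from [cluster_scan()].
#' @param ... Unused.
#' @return A ggplot with one panel per validation index.
#' @export
autoplot.aco_scan <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("k", "silhouette", "davies_bouldin") |>
    tidyr::pivot_longer(-"k", names_to = "index", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$k, .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "number of clusters k", y = NULL,
                  title = "Internal validation across cluster counts") +
    ggplot2::theme_minimal()
}

#' Plot a benchmark comparison
#'
#' @param object An `aco_benchmark` from [benchmark_algorithms()].
#' @param ... Unused.
#' @return A ggplot of mean silhouette and Davies-Bouldin per algorithm
#'   with +/- 1 sd error bars.
#' @export
autoplot.aco_benchmark <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(algorithm = tab$algorithm, index = "silhouette",
                   value = tab$mean_silhouette, sd = tab$sd_silhouette),
    tibble::tibble(algorithm = tab$algorithm, index = "davies_bouldin",
                   value = tab$mean_db, sd = tab$sd_db)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$algorithm, .data$value)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$value - .data$sd,
                                        ymax = .data$value + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Algorithm comparison") +
    ggplot2::theme_minimal()
}

#' Plot a tuning result
#'
#' @param object An `aco_tuning` from [aco_grid_search()].
#' @param top Number of best-ranked combinations to show.
#' @param ... Unused.
#' @return A ggplot of mean silhouette (with +/- 1 sd) for the top
#'   combinations.
#' @export
autoplot.aco_tuning <- function(object, top = 15L, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::slice_min(.data$rank, n = top) |>
    dplyr::mutate(combo = sprintf("m=%d T=%d rho=%.1f tau0=%.1f a=%g b=%g",
                                  .data$m, .data$iterations, .data$rho,
                                  .data$tau0, .data$alpha, .data$beta))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_silhouette,
                                   stats::reorder(.data$combo, .data$mean_silhouette))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_silhouette - .data$sd_silhouette,
                                         xmax = .data$mean_silhouette + .data$sd_silhouette),
                            height = 0.2) +
    ggplot2::labs(x = "mean silhouette", y = NULL,
                  title = "Best parameter combinations") +
    ggplot2::theme_minimal()
}
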