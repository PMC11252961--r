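#' Standard ant colony tuning grid
#'
#' The reference parameter grid for the clustering engine: ant counts
#' \{10, 20, 50\}, iteration budgets \{100, 500, 1000\}, evaporation
#' coefficients \{0.1, 0.5, 0.9\}, initial pheromone levels
#' \{1.0, 0.5, 0.1\}, and pheromone/heuristic exponents alpha, beta each
#' in \{2, 3, 4\} — 729 combinations in total.
#'
#' @return A named list of class `aco_grid` with components `ants`,
#'   `iterations`, `rho`, `tau0`, `alpha`, `beta`.
#' @export
default_grid <- function() {
  structure(
    list(ants = c(10, 20, 50),
         iterations = c(100, 500, 1000),
         rho = c(0.1, 0.5, 0.9),
         tau0 = c(1.0, 0.5, 0.1),
         alpha = c(2, 3, 4),
         beta = c(2, 3, 4)),
    class = "aco_grid"
  )
}

#' Grid search over ant colony parameters
#'
#' Evaluates every combination of the grid with `n_repeats` seeded runs of
#' [aco_cluster()] (repeat seeds are shared across combinations, pairing
#' the comparisons) and ranks combinations by mean silhouette, breaking
#' ties by mean Davies-Bouldin index. The whole search is a pure function
#' of `(data, grid, k, n_repeats, seed)`.
#'
#' A `max_evaluations` cap bounds desk-scale runtime on the full 729-cell
#' grid: when set and exceeded, a seeded uniform subsample of combinations
#' is evaluated instead (the rows report which).
#'
#' @param data Feature table tibble (cleaned, typically standardized).
#' @param grid An `aco_grid` (see [default_grid()]) or a compatible named
#'   list of value vectors.
#' @param k Cluster count.
#' @param n_repeats Seeded repeats per combination.
#' @param seed Master seed.
#' @param max_evaluations Optional cap on the number of combinations
#'   evaluated; `NULL` evaluates all.
#' @param metric Distance metric.
#' @return A tibble of class `aco_tuning`, one row per evaluated
#'   combination (`m`, `iterations`, `rho`, `tau0`, `alpha`, `beta`,
#'   `mean_silhouette`, `sd_silhouette`, `mean_db`, `sd_db`, `mean_cost`,
#'   `n_repeats`, `rank`), sorted by rank, with `best_by_silhouette` and
#'   `best_by_db` attributes holding the winning rows.
#' @export
aco_grid_search <- function(data, grid = default_grid(), k = 3L,
                            n_repeats = 5L, seed = 1L,
                            max_evaluations = NULL, metric = "euclidean") {
  need <- c("ants", "iterations", "rho", "tau0", "alpha", "beta")
  if (!all(need %in% names(grid)) || any(lengths(grid[need]) == 0L)) {
    abort("grid must provide non-empty ants, iterations, rho, tau0, alpha, beta")
  }
  combos <- tidyr::expand_grid(
    m = as.integer(grid$ants), iterations = as.integer(grid$iterations),
    rho = grid$rho, tau0 = grid$tau0, alpha = grid$alpha, beta = grid$beta
  )
  if (!is.null(max_evaluations) && nrow(combos) > max_evaluations) {
    keep <- with_seed(seed_stream(seed, "grid_subsample"),
                      sort(sample.int(nrow(combos), max_evaluations)))
    combos <- combos[keep, , drop = FALSE]
  }
  d <- feature_distances(data, metric)
  repeat_seeds <- vapply(seq_len(n_repeats), function(r) seed_stream(seed, "tune", r),
                         integer(1))
  eval_combo <- function(m, iterations, rho, tau0, alpha, beta) {
    res <- purrr::map(repeat_seeds, function(rs) {
      cfg <- aco_config(m = m, iterations = iterations, rho = rho, tau0 = tau0,
                        alpha = alpha, beta = beta, k = k, seed = rs)
      fit <- aco_cluster(data, config = cfg, dist = d)
      c(sil = silhouette_score(d, fit$labels),
        db = davies_bouldin(data, fit$labels),
        cost = fit$best$cost)
    })
    res <- do.call(rbind, res)
    tibble::tibble(mean_silhouette = mean(res[, "sil"]), sd_silhouette = sd(res[, "sil"]),
                   mean_db = mean(res[, "db"]), sd_db = sd(res[, "db"]),
                   mean_cost = mean(res[, "cost"]), n_repeats = n_repeats)
  }
  out <- dplyr::bind_cols(combos, purrr::pmap_dfr(combos, eval_combo))
  out <- out |>
    dplyr::arrange(dplyr::desc(.data$mean_silhouette), .data$mean_db) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "best_by_silhouette") <- out[1, ]
  attr(out, "best_by_db") <- out[which.min(out$mean_db), ]
  attr(out, "config_hash") <- config_hash(list(grid, k, n_repeats, seed))
  class(out) <- c("aco_tuning", class(out))
  out
}
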