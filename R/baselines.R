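#' K-means comparator
#'
#' Standard Lloyd refinement (delegated to [stats::kmeans()]) started from
#' greedy-spreading centers: the first center is drawn uniformly, each
#' subsequent one with probability proportional to the squared distance to
#' the nearest chosen center. The best of `n_init` seeded restarts by
#' within-cluster sum of squares is returned; identical seeds give
#' identical results.
#'
#' @param data Feature table tibble or numeric matrix (no missing entries).
#' @param k Number of clusters (`k <= n`).
#' @param n_init Number of restarts.
#' @param seed Integer seed.
#' @return A list with `cluster` (named integer assignment), `inertia`
#'   (total within-cluster sum of squares), `centers` and
#'   `inertia_trace` (best-so-far inertia after each restart,
#'   non-increasing).
#' @export
kmeans_cluster <- function(data, k, n_init = 10L, seed = 1L) {
  m <- if (is.matrix(data)) data else feature_matrix(data)
  check_no_missing(m, "feature table")
  n <- nrow(m)
  if (k > n) abort(sprintf("k = %d exceeds the number of samples (%d)", k, n))
  if (k == n) { # every point its own cluster; kmeans() rejects this corner
    return(list(cluster = setNames(seq_len(n), rownames(m)), inertia = 0,
                centers = m, inertia_trace = 0))
  }
  best <- NULL
  trace <- numeric(n_init)
  for (r in seq_len(n_init)) {
    centers <- with_seed(seed_stream(seed, "kmeans", r),
                         spread_centers(m, k))
    fit <- suppressWarnings(stats::kmeans(m, centers = centers,
                                          iter.max = 100L, algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    trace[r] <- best$tot.withinss
  }
  list(cluster = setNames(as.integer(best$cluster), rownames(m)),
       inertia = best$tot.withinss, centers = best$centers,
       inertia_trace = trace)
}

# Greedy-spreading (k-means++-style) center seeding.
spread_centers <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(m, 2L, m[idx[1], ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(m, 2L, m[idx[j], ])^2))
    }
  }
  m[idx, , drop = FALSE] + 1e-10 * seq_len(k) # break exact duplicates
}

#' DBSCAN comparator
#'
#' Density-based clustering on the pairwise distance matrix: points with at
#' least `min_pts` neighbours within `eps` (themselves included) are core
#' points; density-connected cores form clusters and reachable non-core
#' points join them as border points. Unreachable points are flagged as
#' noise (`cluster 0`). Determinism: points are expanded in index order and
#' a border point joins the first cluster that reaches it.
#'
#' When `eps` is `NULL` it defaults to the 90th percentile of the distances
#' to each point's `min_pts`-th nearest neighbour, a standard
#' k-distance-curve heuristic.
#'
#' @param data Feature table tibble or numeric matrix.
#' @param eps Neighbourhood radius (> 0), or `NULL` for the heuristic.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @param dist Optional precomputed distance matrix.
#' @param metric Distance metric when `dist` is `NULL`.
#' @return A list with `cluster` (0 = noise), `n_noise`, `eps`, `min_pts`.
#' @export
dbscan_cluster <- function(data, eps = NULL, min_pts = 4L, dist = NULL,
                           metric = "euclidean") {
  if (is.null(dist)) dist <- feature_distances(data, metric)
  n <- nrow(dist)
  if (min_pts < 1L) abort("min_pts must be >= 1")
  if (is.null(eps)) {
    kth <- apply(dist, 1L, function(row) sort(row)[min(min_pts + 1L, n)])
    eps <- as.numeric(quantile(kth, 0.9))
  }
  if (eps <= 0) abort("eps must be > 0")
  neighbours <- lapply(seq_len(n), function(i) which(dist[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_pts
  labels <- integer(n) # 0 = unassigned/noise
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- neighbours[[i]]
    while (length(frontier) > 0L) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, neighbours[[j]][labels[neighbours[[j]]] == 0L])
      }
    }
  }
  ids <- rownames(dist) %||% as.character(seq_len(n))
  list(cluster = setNames(labels, ids), n_noise = sum(labels == 0L),
       eps = eps, min_pts = as.integer(min_pts))
}

#' Benchmark the ant colony against k-means and DBSCAN
#'
#' Runs each algorithm `n_repeats` times on the same data with paired
#' derived seeds and reports the mean and standard deviation of the
#' silhouette coefficient and Davies-Bouldin index. DBSCAN noise points
#' are excluded from its metric computation and the mean exclusion count
#' is reported; repeats where DBSCAN leaves fewer than 2 clusters score
#' `NA` and are dropped from its averages.
#'
#' @param data Feature table tibble (cleaned, typically standardized).
#' @param k Cluster count for the ant colony and k-means.
#' @param n_repeats Number of seeded repeats per algorithm.
#' @param seed Master seed; repeat `r` uses a derived seed shared by all
#'   algorithms.
#' @param config Base [aco_config()] for the ant colony runs.
#' @param eps,min_pts DBSCAN parameters (see [dbscan_cluster()]).
#' @param metric Distance metric.
#' @return A tibble of class `aco_benchmark`, one row per algorithm, with
#'   the per-repeat results in the `"runs"` attribute and the config hash
#'   in `config_hash`. Plot with [autoplot()].
#' @export
benchmark_algorithms <- function(data, k = 3L, n_repeats = 20L, seed = 1L,
                                 config = aco_config(), eps = NULL,
                                 min_pts = 4L, metric = "euclidean") {
  d <- feature_distances(data, metric)
  hash <- config_hash(list(config, k, eps, min_pts, metric))
  score <- function(labels, keep = NULL) {
    if (is.null(keep)) keep <- rep(TRUE, length(labels))
    if (sum(keep) < 3L || length(unique(labels[keep])) < 2L) {
      return(c(silhouette = NA_real_, db = NA_real_))
    }
    sub <- d[keep, keep, drop = FALSE]
    c(silhouette = silhouette_score(sub, labels[keep]),
      db = davies_bouldin(feature_matrix(data)[keep, , drop = FALSE], labels[keep]))
  }
  runs <- purrr::map(seq_len(n_repeats), function(r) {
    rs <- seed_stream(seed, "benchmark", r)
    cfg <- config; cfg$seed <- rs
    aco <- aco_cluster(data, k = k, config = cfg, dist = d)
    km <- kmeans_cluster(data, k = k, seed = rs)
    db <- dbscan_cluster(data, eps = eps, min_pts = min_pts, dist = d)
    keep <- db$cluster != 0L
    tibble::tibble(
      algorithm = c("aco", "kmeans", "dbscan"),
      repeat_id = r, seed = rs,
      silhouette = c(score(aco$labels)[1], score(km$cluster)[1], score(db$cluster, keep)[1]),
      davies_bouldin = c(score(aco$labels)[2], score(km$cluster)[2], score(db$cluster, keep)[2]),
      noise_excluded = c(0L, 0L, db$n_noise)
    )
  })
  runs <- dplyr::bind_rows(runs)
  out <- runs |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(
      mean_silhouette = mean(.data$silhouette, na.rm = TRUE),
      sd_silhouette = sd(.data$silhouette, na.rm = TRUE),
      mean_db = mean(.data$davies_bouldin, na.rm = TRUE),
      sd_db = sd(.data$davies_bouldin, na.rm = TRUE),
      mean_noise_excluded = mean(.data$noise_excluded),
      n_valid = sum(!is.na(.data$silhouette)),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_repeats = n_repeats, config_hash = hash) |>
    dplyr::arrange(factor(.data$algorithm, levels = c("aco", "kmeans", "dbscan")))
  attr(out, "runs") <- runs
  class(out) <- c("aco_benchmark", class(out))
  out
}
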