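#' Initialize the pheromone matrix
#'
#' Constant initialization: every off-diagonal trail starts at `tau0`,
#' diagonal zero. An optional uniform +/-10% jitter around `tau0` is
#' available for experiments with randomized starting trails.
#'
#' @param n Number of samples (>= 2).
#' @param tau0 Initial trail intensity (> 0).
#' @param jitter Apply the +/-10% symmetric jitter?
#' @param seed Seed used only when `jitter = TRUE`.
#' @return An `n x n` symmetric matrix with zero diagonal.
#' @export
init_pheromone <- function(n, tau0, jitter = FALSE, seed = 1L) {
  if (n < 2L) abort("n must be >= 2")
  if (tau0 <= 0) abort("tau0 must be > 0")
  tau <- matrix(tau0, n, n)
  if (jitter) {
    u <- with_seed(seed_stream(seed, "tau_jitter"),
                   matrix(stats::runif(n * n), n, n))
    tau <- tau * (1 + 0.2 * (u - 0.5))
    tau[lower.tri(tau)] <- t(tau)[lower.tri(tau)]
  }
  diag(tau) <- 0
  tau
}

#' Transition probabilities of an ant's next step
#'
#' An ant at `current` moves to an unvisited point `j` with probability
#' proportional to `tau(current, j)^alpha * eta(current, j)^beta`, where the
#' heuristic desirability is the inverse distance
#' `eta = 1 / (dist + eps_d)`. Closer points and points on stronger trails
#' are favoured.
#'
#' @param current Index of the ant's current point.
#' @param visited Integer vector of already visited point indices
#'   (including `current`).
#' @param tau Pheromone matrix.
#' @param dist Distance matrix.
#' @param alpha,beta Influence exponents (see [aco_config()]).
#' @param eps_d Guard added to distances before inversion.
#' @return A named numeric vector of probabilities over the unvisited
#'   points, summing to 1.
#' @export
transition_probabilities <- function(current, visited, tau, dist,
                                     alpha = 2, beta = 2, eps_d = 1e-10) {
  n <- nrow(tau)
  unvisited <- setdiff(seq_len(n), visited)
  if (length(unvisited) == 0L) abort("no unvisited points remain")
  logw <- alpha * log(tau[current, unvisited]) -
    beta * log(dist[current, unvisited] + eps_d)
  w <- exp(logw - max(logw))
  p <- w / sum(w)
  setNames(p, unvisited)
}

#' Construct one ant path
#'
#' Starts at a uniformly drawn point and repeatedly samples the next point
#' from [transition_probabilities()] until every point has been visited.
#' Each `(seed, iteration, ant)` triple addresses an independent random
#' substream, so the same triple always reproduces the same path.
#'
#' @param tau Pheromone matrix.
#' @param dist Distance matrix.
#' @param alpha,beta,eps_d See [aco_config()].
#' @param seed Master seed.
#' @param iteration,ant Substream keys (1-based).
#' @return An integer permutation of `1:n` (the visiting order).
#' @export
construct_path <- function(tau, dist, alpha = 2, beta = 2, eps_d = 1e-10,
                           seed = 1L, iteration = 1L, ant = 1L) {
  stopifnot(nrow(tau) == nrow(dist), nrow(tau) >= 2L)
  cpp_construct_path(tau, dist, alpha, beta, eps_d,
                     as.integer(seed), as.integer(iteration), as.integer(ant))
}

#' Extract a k-cluster partition from a path
#'
#' Among the `n - 1` consecutive edges of the path, the `k - 1` longest are
#' cut (ties resolved by the earliest path position); the contiguous
#' segments between cuts become the clusters, labelled 1..k in path order.
#' Every cluster is non-empty by construction.
#'
#' @param path Integer permutation of `1:n`.
#' @param dist Distance matrix.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A list with `labels` (length-n integer cluster assignment) and
#'   `cut_edges` (the 1-based path positions after which a cut occurs).
#' @export
path_to_partition <- function(path, dist, k) {
  n <- length(path)
  if (k < 1L || k > n) abort(sprintf("k must be between 1 and %d", n))
  cpp_path_to_partition(as.integer(path), dist, as.integer(k))
}

#' Cost of a partition
#'
#' The clustering objective driving pheromone reinforcement: the average
#' over samples of the mean distance to the other members of their own
#' cluster, i.e. the size-weighted mean pairwise within-cluster distance
#' `(1/n) * sum_c |c| * meanpair(c)`. Tight clusters have low cost;
#' members of singleton clusters contribute zero. The size weighting keeps
#' the objective honest: isolating a few points cannot hide the spread of
#' a large residual cluster.
#'
#' @param labels Integer cluster assignment (values `1..k`).
#' @param dist Distance matrix.
#' @return A non-negative scalar.
#' @export
solution_cost <- function(labels, dist) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(dist))
  n <- length(labels)
  cost <- 0
  for (c in unique(labels)) {
    idx <- which(labels == c)
    if (length(idx) >= 2L) {
      cost <- cost + length(idx) * mean(dist[idx, idx][upper.tri(dist[idx, idx])])
    }
  }
  cost / n
}

#' One pheromone update step
#'
#' Applies the trail update rule: every entry first evaporates to
#' `(1 - rho) * tau`, then each ant deposits `Q / (cost + eps_d)` on every
#' *uncut* edge of its path (cut edges and unused edges only evaporate).
#' All entries are floored at `tau_min` to preserve positivity.
#'
#' @param tau Pheromone matrix.
#' @param solutions List of ant solutions, each a list with `path`,
#'   `cut_edges` and `cost` (as produced by [construct_path()],
#'   [path_to_partition()] and [solution_cost()]).
#' @param rho Evaporation coefficient in (0, 1).
#' @param Q Deposit scale.
#' @param eps_d,tau_min Numerical guards (see [aco_config()]).
#' @return A list with the updated `tau` and `max_change`, the maximum
#'   relative entry change of the step.
#' @export
update_pheromone <- function(tau, solutions, rho, Q = 1.0,
                             eps_d = 1e-10, tau_min = 1e-12) {
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)")
  if (length(solutions) == 0L) abort("need at least one ant solution")
  paths <- lapply(solutions, function(s) as.integer(s$path))
  cuts <- lapply(solutions, function(s) as.integer(s$cut_edges %||% integer()))
  costs <- vapply(solutions, function(s) as.double(s$cost), numeric(1))
  cpp_update_pheromone(tau, paths, cuts, costs, rho, Q, eps_d, tau_min)
}

#' Cluster a feature table with an ant colony
#'
#' The package's core engine. Pairwise distances over the (cleaned,
#' typically standardized) features define the terrain; `m` ants per
#' iteration build Hamiltonian paths biased by pheromone trails and inverse
#' distance, each path is cut into `k` contiguous clusters at its longest
#' edges, and trails evaporate and are reinforced in proportion to
#' partition quality. Iteration stops at the budget or as soon as the
#' maximum relative pheromone change drops below `epsilon`. The best
#' partition across all iterations is returned.
#'
#' @param data A feature table tibble with no missing entries, or a numeric
#'   matrix.
#' @param k Number of clusters; overrides `config$k` when given.
#' @param config An [aco_config()].
#' @param metric Distance metric passed to [feature_distances()].
#' @param dist Optional precomputed distance matrix (skips `metric`).
#' @return An object of class `aco_fit` with elements `labels` (named
#'   integer assignment), `best` (path, cut edges, cost, iteration),
#'   `history` (per-iteration tibble of best cost, mean cost and pheromone
#'   change rate), `converged_at`, `config`, `dist` and `data`. Use
#'   [tidy()], [glance()], [augment()] and [autoplot()] on it.
#' @export
#' @examples
#' athletes <- simulate_athletes(default_athlete_spec(seed = 7))
#' fit <- athletes |>
#'   standardize_features() |>
#'   aco_cluster(k = 3, config = aco_config(iterations = 50, seed = 7))
#' glance(fit)
aco_cluster <- function(data, k = NULL, config = aco_config(),
                        metric = "euclidean", dist = NULL) {
  stopifnot(inherits(config, "aco_config"))
  if (!is.null(k)) config$k <- as.integer(k)
  if (is.null(dist)) dist <- feature_distances(data, metric)
  n <- nrow(dist)
  if (n < 2L) abort("need at least 2 samples")
  if (config$k > n) abort(sprintf("k = %d exceeds the number of samples (%d)", config$k, n))

  res <- cpp_aco_run(dist, config$m, config$iterations, config$rho,
                     config$tau0, config$alpha, config$beta, config$Q,
                     config$k, config$epsilon, config$seed,
                     config$tau_min, config$eps_d, config$init_jitter)

  ids <- rownames(dist) %||% as.character(seq_len(n))
  history <- tibble::tibble(
    iteration = seq_len(nrow(res$history)),
    best_cost = res$history[, 1],
    mean_cost = res$history[, 2],
    max_pheromone_change = res$history[, 3]
  )
  structure(
    list(labels = setNames(as.integer(res$best_labels), ids),
         best = list(path = res$best_path, cut_edges = res$best_cut_edges,
                     cost = res$best_cost, iteration = res$best_iteration),
         history = history,
         converged_at = if (is.na(res$converged_at)) NA_integer_ else res$converged_at,
         iterations_run = res$iterations_run,
         tau = res$tau,
         config = config,
         dist = dist,
         data = if (is.data.frame(data)) tibble::as_tibble(data) else NULL),
    class = "aco_fit"
  )
}
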