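#' Ant colony clustering configuration
#'
#' Collects every tunable of the ant colony clustering engine. The
#' defaults are the middle of the standard tuning grid (see
#' [default_grid()]): 20 ants, slow evaporation, balanced pheromone and
#' distance influence.
#'
#' @param m Number of ants per iteration.
#' @param iterations Maximum number of colony iterations (`T`); must be
#'   >= 1.
#' @param rho Pheromone evaporation (volatilization) coefficient in (0, 1):
#'   each iteration every trail is first multiplied by `1 - rho`.
#' @param tau0 Initial pheromone level on every edge (> 0).
#' @param alpha Pheromone influence exponent (>= 0) on the trail intensity.
#' @param beta Heuristic influence exponent (>= 0) on the inverse distance
#'   desirability `1 / (d + eps_d)`.
#' @param Q Deposit scale: each ant adds `Q / (cost + eps_d)` to the uncut
#'   edges of its path.
#' @param k Number of clusters to extract from each path (>= 1).
#' @param epsilon Convergence threshold on the maximum relative pheromone
#'   change per iteration; the run stops early once the change rate falls
#'   below it.
#' @param seed Master seed; each (iteration, ant) pair draws from its own
#'   derived substream, so changing `m` or `iterations` does not reshuffle
#'   unrelated draws.
#' @param tau_min Numerical floor keeping all trails positive.
#' @param eps_d Small constant guarding divisions by zero distance or cost.
#' @param init_jitter If `TRUE`, initial trails get a uniform +/-10% jitter
#'   around `tau0` instead of a constant fill.
#' @return An object of class `aco_config`.
#' @export
aco_config <- function(m = 20L, iterations = 200L, rho = 0.1, tau0 = 1.0,
                       alpha = 2, beta = 2, Q = 1.0, k = 3L,
                       epsilon = 1e-4, seed = 1L,
                       tau_min = 1e-12, eps_d = 1e-10, init_jitter = FALSE) {
  if (m < 1L) abort("m (ant count) must be >= 1")
  if (iterations < 1L) abort("iterations must be >= 1")
  if (rho <= 0 || rho >= 1) abort("rho must be in (0, 1)")
  if (tau0 <= 0) abort("tau0 must be > 0")
  if (alpha < 0 || beta < 0) abort("alpha and beta must be >= 0")
  if (Q <= 0) abort("Q must be > 0")
  if (k < 1L) abort("k must be >= 1")
  if (epsilon <= 0) abort("epsilon must be > 0")
  structure(
    list(m = as.integer(m), iterations = as.integer(iterations),
         rho = rho, tau0 = tau0, alpha = alpha, beta = beta, Q = Q,
         k = as.integer(k), epsilon = epsilon, seed = as.integer(seed),
         tau_min = tau_min, eps_d = eps_d, init_jitter = isTRUE(init_jitter)),
    class = "aco_config"
  )
}

#' @export
print.aco_config <- function(x, ...) {
  cat(sprintf(paste0("<aco_config> m=%d T=%d rho=%.3g tau0=%.3g alpha=%.3g ",
                     "beta=%.3g Q=%.3g k=%d epsilon=%.3g seed=%d\n"),
              x$m, x$iterations, x$rho, x$tau0, x$alpha, x$beta, x$Q,
              x$k, x$epsilon, x$seed))
  invisible(x)
}
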