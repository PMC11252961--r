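# The ant colony engine: distances, pheromone mechanics, path
# construction, partition extraction, cost, and the full run contract.

test_that("feature_distances matches hand values and a brute-force loop", {
  m <- rbind(c(0, 0), c(3, 4))
  rownames(m) <- c("a", "b")
  d <- feature_distances(m)
  expect_equal(d["a", "b"], 5.0)
  expect_equal(diag(d), c(a = 0, b = 0))

  m <- rbind(c(1, 2), c(1, 2))
  expect_equal(feature_distances(m)[1, 2], 0)

  withr::local_seed(8)
  m <- matrix(rnorm(10), 5, 2)
  d <- feature_distances(m)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((m[i, ] - m[j, ])^2)), tolerance = 1e-12)
  }
  dm <- feature_distances(m, "manhattan")
  expect_equal(dm[1, 2], sum(abs(m[1, ] - m[2, ])), tolerance = 1e-12)
  dc <- feature_distances(m, "cosine")
  expect_true(isSymmetric(dc) && all(diag(dc) == 0) && all(dc >= 0))
  expect_error(feature_distances(m, "mahalanobis"))
})

test_that("init_pheromone fills constant tau0 with zero diagonal", {
  tau <- init_pheromone(4, 1.0)
  expect_equal(diag(tau), rep(0, 4))
  expect_equal(sum(tau == 1.0), 12L)
  tau <- init_pheromone(4, 0.5)
  expect_true(all(tau[row(tau) != col(tau)] == 0.5))
  expect_error(init_pheromone(4, 0), "tau0")
  expect_error(init_pheromone(1, 1), "n must")
  # optional jitter stays within +/-10% and symmetric
  tau <- init_pheromone(6, 2, jitter = TRUE, seed = 4)
  off <- tau[row(tau) != col(tau)]
  expect_true(all(off >= 1.8 & off <= 2.2))
  expect_true(isSymmetric(tau))
})

test_that("transition probabilities follow tau^alpha * eta^beta", {
  tau <- init_pheromone(4, 1)
  d <- matrix(1, 4, 4); diag(d) <- 0
  p <- transition_probabilities(1, visited = 1, tau, d)
  expect_equal(unname(p), rep(1 / 3, 3))

  p <- transition_probabilities(1, visited = 1:3, tau, d)
  expect_equal(unname(p), 1)

  # hand case: alpha = beta = 2, (tau 0.5, d 1) vs (tau 1.0, d 2)
  # weights 0.5^2 * 1 = 0.25 and 1 * 0.5^2 = 0.25 -> 50/50
  tau <- init_pheromone(3, 1); tau[1, 2] <- tau[2, 1] <- 0.5
  d <- matrix(0, 3, 3); d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 2
  d[2, 3] <- d[3, 2] <- 1
  p <- transition_probabilities(1, visited = 1, tau, d, alpha = 2, beta = 2)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(transition_probabilities(1, visited = 1:3, tau, d), "unvisited")
})

test_that("transition probabilities sum to one and increase with tau", {
  withr::local_seed(21)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    tau <- init_pheromone(n, 1, jitter = TRUE, seed = rep)
    d <- feature_distances(matrix(rnorm(n * 2), n, 2))
    visited <- sample(n, sample(n - 1, 1))
    cur <- visited[1]
    p <- transition_probabilities(cur, visited, tau, d,
                                  alpha = runif(1, 0, 4), beta = runif(1, 0, 4))
    expect_lt(abs(sum(p) - 1), 1e-12)
    # raising tau on one candidate edge never lowers its probability
    j <- as.integer(names(p)[1])
    tau2 <- tau; tau2[cur, j] <- tau2[j, cur] <- tau[cur, j] * 3
    p2 <- transition_probabilities(cur, visited, tau2, d, alpha = 2, beta = 1)
    p1 <- transition_probabilities(cur, visited, tau, d, alpha = 2, beta = 1)
    expect_gte(p2[as.character(j)], p1[as.character(j)])
  }
})

test_that("construct_path samples full permutations from the right law", {
  # n = 2: both orderings occur across seeds
  tau <- init_pheromone(2, 1)
  d <- matrix(c(0, 1, 1, 0), 2)
  starts <- vapply(1:100, function(s) construct_path(tau, d, seed = s)[1], integer(1))
  expect_setequal(unique(starts), 1:2)

  # alpha = beta = 0: all 6 permutations of n = 3 equally likely
  tau <- init_pheromone(3, 1)
  d <- feature_distances(matrix(c(0, 0, 1, 0, 0.3, 2), 3, 2))
  perms <- vapply(1:6000, function(s) {
    paste(construct_path(tau, d, alpha = 0, beta = 0, seed = s), collapse = "")
  }, character(1))
  tab <- table(perms)
  expect_equal(length(tab), 6L)
  expect_gt(chisq.test(tab)$p.value, 0.001)

  # very large beta with well-separated distinct distances: the path is
  # the greedy nearest-neighbour tour (geometric spacing keeps every
  # candidate-distance ratio large, so the argmax step dominates)
  m <- matrix(3^(0:5), ncol = 1)
  d <- feature_distances(m)
  for (s in 1:10) {
    p <- construct_path(init_pheromone(6, 1), d, alpha = 1, beta = 60, seed = s)
    expect_equal(as.integer(p), greedy_nn_path(d, p[1]))
  }
})

test_that("path_to_partition cuts the largest edges with a fixed tie rule", {
  # 1-D points with consecutive path gaps 1, 9, 1, 8, 1
  m <- matrix(c(0, 1, 10, 11, 19, 20), ncol = 1)
  d <- feature_distances(m)
  out <- path_to_partition(1:6, d, k = 3)
  expect_equal(out$labels, c(1, 1, 2, 2, 3, 3))
  expect_equal(out$cut_edges, c(2L, 4L))

  expect_equal(path_to_partition(1:6, d, k = 1)$labels, rep(1L, 6))
  expect_equal(path_to_partition(1:6, d, k = 6)$labels, 1:6)

  # all edges equal: ties cut at the earliest positions
  deq <- matrix(1, 4, 4); diag(deq) <- 0
  out <- path_to_partition(1:4, deq, k = 3)
  expect_equal(out$cut_edges, c(1L, 2L))
  expect_error(path_to_partition(1:4, deq, k = 5), "between")

  # agrees with an independent restatement on fuzzed paths
  withr::local_seed(13)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    dd <- feature_distances(matrix(rnorm(n * 3), n, 3))
    path <- sample(n)
    k <- sample(2:(n - 1), 1)
    got <- path_to_partition(path, dd, k)
    expect_equal(got$labels, brute_path_partition(path, dd, k))
    expect_equal(length(unique(got$labels)), k) # k non-empty clusters
  }
})

test_that("solution_cost is the size-weighted within-cluster cohesion", {
  d2 <- matrix(c(0, 4, 4, 0), 2)
  expect_equal(solution_cost(c(1, 1), d2), 4.0)
  expect_equal(solution_cost(c(1, 2), d2), 0)

  # three 2-point clusters with within-pair distances 1 each
  m <- matrix(c(0, 1, 10, 11, 19, 20), ncol = 1)
  d <- feature_distances(m)
  expect_equal(solution_cost(c(1, 1, 2, 2, 3, 3), d), 1.0)

  # R and C++ implementations agree on fuzzed partitions
  withr::local_seed(17)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    dd <- feature_distances(matrix(rnorm(n * 2), n, 2))
    labels <- sample(1:3, n, replace = TRUE)
    labels[1:3] <- 1:3
    expect_equal(solution_cost(labels, dd),
                 antclust:::cpp_solution_cost(as.integer(labels), dd),
                 tolerance = 1e-12)
    expect_equal(solution_cost(labels, dd), brute_cost(labels, dd),
                 tolerance = 1e-12)
  }
})

test_that("pheromone update follows evaporation plus per-ant deposit", {
  n <- 4
  tau <- init_pheromone(n, 1.0)
  d <- matrix(1, n, n); diag(d) <- 0
  # all edges cut (k = n): pure evaporation at rho = 0.5
  sol <- list(path = 1:4, cut_edges = 1:3, cost = 1)
  out <- update_pheromone(tau, list(sol), rho = 0.5)
  expect_true(all(out$tau[row(out$tau) != col(out$tau)] == 0.5))
  expect_equal(out$max_change, 0.5)

  # single ant, rho 0.1, Q 1, cost 1, one uncut edge: 0.9 + 1/(1 + eps) ~ 1.9
  tau3 <- init_pheromone(3, 1.0)
  sol <- list(path = 1:3, cut_edges = 2L, cost = 1)
  out <- update_pheromone(tau3, list(sol), rho = 0.1, Q = 1)
  expect_equal(out$tau[1, 2], 1.9, tolerance = 1e-9)
  expect_equal(out$tau[2, 1], 1.9, tolerance = 1e-9)
  expect_equal(out$tau[2, 3], 0.9)
  expect_equal(out$tau[1, 3], 0.9)

  # deposit-free decay is exactly geometric until the floor binds
  for (rho in c(0.1, 0.5, 0.9)) {
    tau_t <- init_pheromone(4, 1.0)
    cut_all <- list(path = 1:4, cut_edges = 1:3, cost = 1)
    for (t in 1:20) {
      tau_t <- update_pheromone(tau_t, list(cut_all), rho = rho)$tau
      expect_equal(max(abs(tau_t[1, -1] - max((1 - rho)^t, 1e-12))), 0,
                   tolerance = 1e-12)
    }
  }
  expect_error(update_pheromone(tau, list(sol), rho = 1.2), "rho")
  expect_error(update_pheromone(tau, list(), rho = 0.5), "solution")
})

test_that("pheromone stays symmetric, positive, zero-diagonal through updates", {
  withr::local_seed(31)
  n <- 10
  d <- feature_distances(matrix(rnorm(n * 2), n, 2))
  tau <- init_pheromone(n, 0.5)
  for (t in 1:15) {
    sols <- lapply(1:3, function(a) {
      path <- construct_path(tau, d, seed = 31, iteration = t, ant = a)
      part <- path_to_partition(path, d, 3)
      list(path = path, cut_edges = part$cut_edges,
           cost = solution_cost(part$labels, d))
    })
    tau <- update_pheromone(tau, sols, rho = 0.3)$tau
    expect_true(isSymmetric(tau))
    expect_equal(diag(tau), rep(0, n))
    expect_true(all(tau[row(tau) != col(tau)] > 0))
  }
})

test_that("aco_cluster honours its run contract", {
  x <- fixture_athletes(seed = 7)
  cfg <- aco_config(iterations = 40, seed = 2)
  fit1 <- aco_cluster(x, k = 3, config = cfg)
  fit2 <- aco_cluster(x, k = 3, config = cfg)
  expect_identical(fit1$labels, fit2$labels)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$best, fit2$best)

  expect_lte(nrow(fit1$history), 40)
  expect_equal(fit1$best$cost, min(fit1$history$best_cost))
  expect_equal(sort(unique(unname(fit1$labels))), 1:3)
  expect_equal(as.integer(path_to_partition(fit1$best$path, fit1$dist, 3)$labels),
               unname(fit1$labels))

  expect_error(aco_config(iterations = 0), "iterations")
  expect_error(aco_cluster(x, k = 100, config = cfg), "exceeds")
})

test_that("zero-noise archetypes are recovered exactly for every seed", {
  x <- simulate_athletes(default_athlete_spec(within_sd = 1e-9, seed = 11))
  for (s in 1:5) {
    fit <- aco_cluster(x, k = 3, config = aco_config(m = 20, iterations = 200, seed = s))
    expect_equal(mclust::adjustedRandIndex(fit$labels, x$archetype), 1)
  }
})

test_that("tidy, glance, augment and autoplot work on a fit", {
  x <- fixture_athletes(seed = 7)
  fit <- aco_cluster(x, k = 3, config = aco_config(iterations = 30, seed = 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 60L)
  expect_named(td, c("sample_id", "cluster", "silhouette"))
  g <- glance(fit)
  expect_equal(g$k, 3L)
  expect_equal(g$silhouette, silhouette_score(fit$dist, fit$labels))
  au <- augment(fit)
  expect_s3_class(au$.cluster, "factor")
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "history"), "ggplot")
})
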