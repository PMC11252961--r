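# Independent brute-force reference implementations used as oracles.
# These deliberately use plain double loops and direct formula transcription,
# sharing no code with the package internals they check.

# Per-sample silhouette widths by direct definition.
brute_silhouette <- function(dist, labels) {
  n <- nrow(dist)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(dist[i, own])
    b <- Inf
    for (c in setdiff(ks, labels[i])) {
      b <- min(b, mean(dist[i, labels == c]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

# Davies-Bouldin by direct formula transcription (Euclidean centroids).
brute_davies_bouldin <- function(m, labels) {
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  k <- length(ks)
  centroids <- matrix(0, k, ncol(m))
  sigma <- numeric(k)
  for (c in seq_len(k)) {
    rows <- m[labels == ks[c], , drop = FALSE]
    centroids[c, ] <- colMeans(rows)
    sigma[c] <- mean(apply(rows, 1L, function(r) sqrt(sum((r - centroids[c, ])^2))))
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      worst <- max(worst, (sigma[i] + sigma[j]) / dij)
    }
    total <- total + worst
  }
  total / k
}

# All partitions of 1..n into exactly k non-empty clusters (restricted
# growth strings).
enum_partitions <- function(n, k) {
  res <- list()
  rec <- function(i, labels, used) {
    if (i > n) {
      if (used == k) res[[length(res) + 1L]] <<- labels
      return(invisible())
    }
    for (c in seq_len(min(used + 1L, k))) {
      labels[i] <- c
      rec(i + 1L, labels, max(used, c))
    }
  }
  rec(1L, integer(n), 0L)
  res
}

# Partition cost by direct definition: mean over samples of the mean
# distance to own-cluster peers.
brute_cost <- function(labels, dist) {
  n <- length(labels)
  per_sample <- numeric(n)
  for (i in seq_len(n)) {
    peers <- which(labels == labels[i] & seq_len(n) != i)
    per_sample[i] <- if (length(peers) > 0) mean(dist[i, peers]) else 0
  }
  mean(per_sample)
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Best cluster->label bijection by exhaustive search over the padded
# confusion table; returns the maximum total agreement.
brute_best_agreement <- function(pred, truth) {
  conf <- table(factor(pred), factor(truth))
  side <- max(dim(conf))
  padded <- matrix(0, side, side)
  padded[seq_len(nrow(conf)), seq_len(ncol(conf))] <- conf
  best <- -Inf
  for (perm in all_permutations(seq_len(side))) {
    agree <- sum(padded[cbind(seq_len(side), perm)])
    best <- max(best, agree)
  }
  best
}

# Greedy nearest-neighbour tour from a fixed start (lowest index wins ties).
greedy_nn_path <- function(dist, start) {
  n <- nrow(dist)
  path <- integer(n)
  visited <- rep(FALSE, n)
  path[1] <- start; visited[start] <- TRUE
  for (s in 2:n) {
    cand <- which(!visited)
    path[s] <- cand[which.min(dist[path[s - 1], cand])]
    visited[path[s]] <- TRUE
  }
  path
}

# Path cutting by direct rule restatement: cut the k-1 largest consecutive
# edges, earliest position on ties, label segments in path order.
brute_path_partition <- function(path, dist, k) {
  n <- length(path)
  lens <- vapply(seq_len(n - 1), function(i) dist[path[i], path[i + 1]], numeric(1))
  ord <- order(-lens, seq_along(lens))
  cut <- sort(ord[seq_len(k - 1)])
  labels <- integer(n)
  seg <- 1L
  labels[path[1]] <- 1L
  for (i in 2:n) {
    if ((i - 1) %in% cut) seg <- seg + 1L
    labels[path[i]] <- seg
  }
  labels
}

# The package's standard 3-archetype fixture.
fixture_athletes <- function(seed = 7, ...) {
  simulate_athletes(default_athlete_spec(seed = seed, ...))
}

# Random labelled point set for fuzz tests.
random_instance <- function(n, d = 2, k = 2) {
  m <- matrix(stats::runif(n * d), n, d)
  rownames(m) <- paste0("p", seq_len(n))
  labels <- sample(rep_len(seq_len(k), n))
  list(m = m, labels = labels, dist = feature_distances(m))
}
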