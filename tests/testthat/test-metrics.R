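# Internal validation (silhouette, Davies-Bouldin), cluster-label
# matching, supervised scores, and the k-scan.

test_that("silhouette reproduces the hand-derived 1-D worked example", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  d <- feature_distances(m)
  s <- silhouette_samples(d, c(1, 1, 2, 2))
  # a = 1 throughout; b = 10.5, 9.5, 9.5, 10.5 -> (b-a)/b
  expect_equal(s$silhouette, c(19 / 21, 17 / 19, 17 / 19, 19 / 21),
               tolerance = 1e-12)
  expect_equal(silhouette_score(d, c(1, 1, 2, 2)), 0.8997494, tolerance = 1e-7)
})

test_that("silhouette handles degenerate geometry and validates input", {
  # all points coincident: a = b = 0 for everyone -> 0 by convention
  m <- matrix(1, 4, 2)
  d <- feature_distances(m)
  expect_equal(silhouette_score(d, c(1, 1, 2, 2)), 0)
  # singleton clusters score 0
  m <- matrix(c(0, 1, 5), ncol = 1)
  s <- silhouette_samples(feature_distances(m), c(1, 1, 2))
  expect_equal(s$silhouette[3], 0)
  expect_error(silhouette_score(d, c(1, 1, 1, 1)), "2 clusters")
  expect_error(silhouette_score(feature_distances(matrix(c(0, 1), 2, 1)), 1:2),
               "3 samples")
})

test_that("silhouette matches the brute-force oracle and stays in [-1, 1]", {
  withr::local_seed(41)
  for (rep in 1:40) {
    inst <- random_instance(n = sample(6:20, 1), d = sample(1:4, 1),
                            k = sample(2:4, 1))
    got <- silhouette_samples(inst$dist, inst$labels)$silhouette
    expect_equal(got, brute_silhouette(inst$dist, inst$labels), tolerance = 1e-12)
    expect_true(all(got >= -1 & got <= 1))
  }
})

test_that("silhouette is invariant to relabeling and distance scaling", {
  withr::local_seed(43)
  inst <- random_instance(12, 3, 3)
  base <- silhouette_score(inst$dist, inst$labels)
  relab <- c(2, 3, 1)[inst$labels]
  expect_equal(silhouette_score(inst$dist, relab), base, tolerance = 1e-12)
  expect_equal(silhouette_score(7.3 * inst$dist, inst$labels), base,
               tolerance = 1e-12)
})

test_that("Davies-Bouldin reproduces hand values and limiting cases", {
  m <- matrix(c(0, 1, 10, 11), ncol = 1)
  # sigma = 0.5 each, centroid distance 10 -> DB = 0.1
  expect_equal(davies_bouldin(m, c(1, 1, 2, 2)), 0.1, tolerance = 1e-12)
  # singletons at distinct positions: zero scatter -> DB = 0
  expect_equal(davies_bouldin(matrix(c(0, 3, 9), ncol = 1), 1:3), 0)
  # shrinking within-cluster spread with fixed centroids decreases DB
  spread <- function(f) davies_bouldin(matrix(c(-f, f, 10 - f, 10 + f), ncol = 1),
                                       c(1, 1, 2, 2))
  expect_lt(spread(0.5), spread(1))
  expect_lt(spread(0.25), spread(0.5))
  expect_error(davies_bouldin(matrix(c(0, 0, 0, 0), ncol = 1), c(1, 1, 2, 2)),
               "centroid")
})

test_that("Davies-Bouldin matches the brute-force oracle and its invariances", {
  withr::local_seed(47)
  for (rep in 1:40) {
    inst <- random_instance(n = sample(6:20, 1), d = sample(2:4, 1),
                            k = sample(2:4, 1))
    got <- davies_bouldin(inst$m, inst$labels)
    expect_equal(got, brute_davies_bouldin(inst$m, inst$labels), tolerance = 1e-12)
    # rigid translation and uniform scaling leave the ratio form unchanged
    shifted <- sweep(inst$m, 2L, rnorm(ncol(inst$m)), `+`)
    expect_equal(davies_bouldin(shifted, inst$labels), got, tolerance = 1e-9)
    expect_equal(davies_bouldin(3.7 * inst$m, inst$labels), got, tolerance = 1e-9)
  }
})

test_that("match_clusters recovers permutations and pads unequal sizes", {
  truth <- rep(1:3, each = 4)
  pred <- c(3, 1, 2)[truth] # pure relabeling
  mp <- match_clusters(pred, truth)
  expect_equal(attr(mp, "agreement"), 12)
  expect_equal(mp$label[match(c("3", "1", "2"), mp$cluster)], c("1", "2", "3"))

  # worked example: truth 1 1 2 2 3 3, pred A A B C C C -> agreement 5
  truth <- c(1, 1, 2, 2, 3, 3)
  pred <- c("A", "A", "B", "C", "C", "C")
  mp <- match_clusters(pred, truth)
  expect_equal(attr(mp, "agreement"), 5)
  expect_equal(mp$label, c("1", "2", "3"))

  # fewer predicted clusters than classes: mapping stays injective
  mp <- match_clusters(c(1, 1, 2, 2, 2, 2), truth)
  expect_equal(anyDuplicated(na.omit(mp$label)), 0L)
  expect_error(match_clusters(1:3, 1:4), "length")
})

test_that("Hungarian matching agrees with exhaustive bijection search", {
  withr::local_seed(53)
  for (rep in 1:30) {
    n <- sample(8:25, 1)
    kp <- sample(2:5, 1); kt <- sample(2:5, 1)
    pred <- sample(kp, n, replace = TRUE)
    truth <- sample(kt, n, replace = TRUE)
    expect_equal(attr(match_clusters(pred, truth), "agreement"),
                 brute_best_agreement(pred, truth))
  }
})

test_that("supervised metrics score mapped partitions correctly", {
  truth <- c(1, 1, 2, 2, 3, 3)
  perfect <- c(2, 2, 3, 3, 1, 1)
  r <- supervised_metrics(perfect, truth)
  expect_equal(r$accuracy, 1)
  expect_equal(r$f1_macro, 1)

  r <- supervised_metrics(c("A", "A", "B", "C", "C", "C"), truth)
  expect_equal(r$accuracy, 5 / 6)

  # all samples in one predicted cluster, 3 balanced classes
  r <- supervised_metrics(rep(1, 6), truth)
  expect_equal(r$accuracy, 1 / 3)
  expect_equal(r$recall_macro, 1 / 3)

  # f1 is the harmonic mean of the macro precision/recall
  withr::local_seed(59)
  for (rep in 1:10) {
    pred <- sample(3, 30, replace = TRUE)
    truth <- sample(3, 30, replace = TRUE)
    r <- supervised_metrics(pred, truth)
    if (r$precision_macro > 0 && r$recall_macro > 0) {
      expect_equal(r$f1_macro,
                   2 * r$precision_macro * r$recall_macro /
                     (r$precision_macro + r$recall_macro),
                   tolerance = 1e-9)
    }
  }
})

test_that("AUC uses centroid softmax scores when data is supplied", {
  x <- fixture_athletes(seed = 7)
  fit <- aco_cluster(x, k = 3, config = aco_config(iterations = 60, seed = 1))
  r_nodata <- supervised_metrics(fit$labels, x$archetype)
  expect_true(is.na(r_nodata$auc_macro))
  r <- supervised_metrics(fit$labels, x$archetype, data = x)
  expect_true(r$auc_macro > 0.9 && r$auc_macro <= 1)
  # explicit scores: a perfectly informative score matrix gives AUC 1
  scores <- outer(as.integer(x$archetype), 1:3, `==`) * 1.0
  r <- supervised_metrics(fit$labels, x$archetype, scores = scores)
  expect_equal(r$auc_macro, 1)
})

test_that("cluster_scan returns one validated row per k with shared hash", {
  x <- fixture_athletes(seed = 7)
  sc <- cluster_scan(x, k_values = 3, config = aco_config(iterations = 30, seed = 1))
  expect_equal(nrow(sc), 1L)
  sc <- cluster_scan(x, k_values = 2:4, config = aco_config(iterations = 30, seed = 1))
  expect_equal(sc$k, 2:4)
  expect_equal(length(unique(sc$config_hash)), 1L)
  expect_true(attr(sc, "recommended_k_silhouette") %in% sc$k)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_error(cluster_scan(x, integer()), "non-empty")
})
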