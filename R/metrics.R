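#' Per-sample silhouette widths
#'
#' For sample `i`, `a(i)` is the mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to any other cluster; the
#' silhouette width is `(b - a) / max(a, b)`, in `[-1, 1]`, higher meaning
#' the sample sits well inside its cluster. Members of singleton clusters
#' get width 0 by convention (`a` is undefined without peers).
#'
#' @param dist Distance matrix.
#' @param labels Cluster assignment (integer or factor, >= 2 clusters,
#'   n >= 3).
#' @return A tibble with `sample_id`, `cluster` and `silhouette`.
#' @seealso [silhouette_score()] for the mean, [davies_bouldin()] for the
#'   companion index.
#' @export
silhouette_samples <- function(dist, labels) {
  n <- nrow(dist)
  labels <- as.integer(factor(labels))
  if (length(labels) != n) abort("labels length must match the distance matrix")
  if (n < 3L) abort("silhouette needs at least 3 samples")
  ks <- sort(unique(labels))
  if (length(ks) < 2L) abort("silhouette needs at least 2 clusters")
  # mean distance from every sample to every cluster, in one pass
  member <- outer(labels, ks, `==`)        # n x k
  sums <- dist %*% member                  # n x k total distance to cluster
  sizes <- colSums(member)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(labels[i], ks)
    if (sizes[own] == 1L) { s[i] <- 0; next }
    a <- sums[i, own] / (sizes[own] - 1L)  # exclude self (dist 0)
    b <- min(sums[i, -own] / sizes[-own])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  tibble::tibble(
    sample_id = rownames(dist) %||% as.character(seq_len(n)),
    cluster = labels, silhouette = s
  )
}

#' Mean silhouette coefficient
#'
#' @inheritParams silhouette_samples
#' @return The mean of the per-sample silhouette widths.
#' @export
silhouette_score <- function(dist, labels) {
  mean(silhouette_samples(dist, labels)$silhouette)
}

#' Davies-Bouldin index
#'
#' For each cluster `i`, the scatter `sigma_i` is the mean Euclidean
#' distance of its members to the cluster centroid; the index is the mean
#' over clusters of the worst ratio
#' `(sigma_i + sigma_j) / d(c_i, c_j)` against any other cluster, where
#' `d(c_i, c_j)` is the Euclidean distance between centroids. Lower is
#' better. Centroid distances are always Euclidean, matching the centroid
#' formulation, regardless of the metric used for clustering.
#'
#' @param data Feature table tibble or numeric matrix (no missing entries).
#' @param labels Cluster assignment with at least 2 clusters.
#' @return A non-negative scalar; coincident centroids are an error.
#' @export
davies_bouldin <- function(data, labels) {
  m <- if (is.matrix(data)) data else feature_matrix(data)
  check_no_missing(m, "feature table")
  labels <- as.integer(factor(labels))
  stopifnot(length(labels) == nrow(m))
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2L) abort("Davies-Bouldin needs at least 2 clusters")
  centroids <- do.call(rbind, lapply(ks, function(c) colMeans(m[labels == c, , drop = FALSE])))
  sigma <- vapply(seq_len(k), function(c) {
    rows <- m[labels == ks[c], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2L, centroids[c, ])^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(centroids))
  if (any(cd[upper.tri(cd)] == 0)) abort("two clusters share a centroid; Davies-Bouldin undefined")
  ratios <- outer(sigma, sigma, `+`) / cd
  diag(ratios) <- -Inf
  mean(apply(ratios, 1L, max))
}

#' Match predicted clusters to true labels
#'
#' Finds the one-to-one assignment of predicted clusters to true classes
#' maximizing total agreement on the confusion table (the optimal
#' assignment problem, solved exactly with the Hungarian algorithm; the
#' smaller side is padded with zero-agreement dummies when cluster and
#' class counts differ, keeping the mapping injective).
#'
#' @param pred Predicted cluster assignment.
#' @param truth True class labels, same length.
#' @return A tibble with `cluster`, `label` and `n_agree` (one row per
#'   matched pair; unmatched clusters map to `NA`), carrying the total
#'   `"agreement"` and the `"confusion"` table as attributes.
#' @export
match_clusters <- function(pred, truth) {
  if (length(pred) != length(truth)) abort("pred and truth must have the same length")
  pf <- factor(pred)
  tf <- factor(truth)
  conf <- table(cluster = pf, label = tf)
  kp <- nlevels(pf); kt <- nlevels(tf)
  side <- max(kp, kt)
  cost <- matrix(0, side, side) # Hungarian minimizes; use negated agreement
  cost[seq_len(kp), seq_len(kt)] <- -unclass(conf)
  assign <- hungarian_assignment(cost)
  rows <- seq_len(kp)
  matched_col <- assign[rows]
  label_out <- ifelse(matched_col <= kt, levels(tf)[matched_col], NA_character_)
  n_agree <- vapply(rows, function(i) {
    if (matched_col[i] <= kt) conf[i, matched_col[i]] else 0L
  }, numeric(1))
  out <- tibble::tibble(cluster = levels(pf), label = label_out,
                        n_agree = as.integer(n_agree))
  attr(out, "agreement") <- sum(n_agree)
  attr(out, "confusion") <- conf
  out
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths),
# exact for square cost matrices; returns the column assigned to each row.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1) # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- Inf; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta; v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Supervised evaluation of a clustering against ground truth
#'
#' Maps predicted clusters to true classes with [match_clusters()], then
#' scores the mapped prediction: accuracy, macro-averaged precision, recall
#' and F1 over the true classes, and (when per-class scores are available)
#' macro one-vs-rest AUC. A per-class precision or recall with an empty
#' denominator counts as 0 in the macro average.
#'
#' Hard clusterings carry no class scores, so by default the AUC score for
#' class `c` is the softmax (temperature 1) of the negative Euclidean
#' distance to the centroid of the cluster mapped to `c`, computed from
#' `data`; pass `scores` to override, or leave both `NULL` to omit AUC.
#'
#' @param pred Predicted cluster assignment.
#' @param truth True class labels, same length.
#' @param scores Optional `n x k_true` matrix of class membership scores
#'   (columns in the order of `levels(factor(truth))`).
#' @param data Optional feature table used to build default centroid-based
#'   scores when `scores` is `NULL`.
#' @return A one-row tibble with `accuracy`, `precision_macro`,
#'   `recall_macro`, `f1_macro`, `auc_macro` (`NA` if no scores), plus the
#'   `"mapping"` and `"confusion"` attributes.
#' @export
supervised_metrics <- function(pred, truth, scores = NULL, data = NULL) {
  mapping <- match_clusters(pred, truth)
  tf <- factor(truth)
  pf <- factor(pred)
  n <- length(truth)
  classes <- levels(tf)
  # translate each predicted cluster to its mapped class (NA if unmatched)
  map <- setNames(mapping$label, mapping$cluster)
  mapped <- unname(map[as.character(pf)])

  acc <- sum(!is.na(mapped) & mapped == as.character(tf)) / n
  per_class <- vapply(classes, function(c) {
    tp <- sum(mapped == c & tf == c, na.rm = TRUE)
    fp <- sum(mapped == c & tf != c, na.rm = TRUE)
    fn <- sum((is.na(mapped) | mapped != c) & tf == c)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    c(prec, rec)
  }, numeric(2))
  precision <- mean(per_class[1, ])
  recall <- mean(per_class[2, ])
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0

  if (is.null(scores) && !is.null(data)) {
    scores <- centroid_softmax_scores(data, mapped, classes)
  }
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    stopifnot(nrow(scores) == n, ncol(scores) == length(classes))
    aucs <- vapply(seq_along(classes), function(j) {
      resp <- as.integer(tf == classes[j])
      if (length(unique(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, j], quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
  }

  out <- tibble::tibble(accuracy = acc, precision_macro = precision,
                        recall_macro = recall, f1_macro = f1,
                        auc_macro = auc)
  attr(out, "mapping") <- mapping
  attr(out, "confusion") <- attr(mapping, "confusion")
  out
}

# Softmax (temperature 1) of negative Euclidean distance to the centroid of
# the cluster mapped to each class; classes with no mapped cluster fall
# back to the global centroid.
centroid_softmax_scores <- function(data, mapped, classes) {
  m <- if (is.matrix(data)) data else feature_matrix(data)
  centroids <- lapply(classes, function(c) {
    rows <- which(!is.na(mapped) & mapped == c)
    if (length(rows) == 0L) colMeans(m) else colMeans(m[rows, , drop = FALSE])
  })
  d <- vapply(centroids, function(ctr) sqrt(rowSums(sweep(m, 2L, ctr)^2)),
              numeric(nrow(m)))
  e <- exp(-(d - apply(d, 1L, max)))
  e / rowSums(e)
}

#' Scan cluster counts with the ant colony engine
#'
#' Runs [aco_cluster()] once per candidate `k` (all runs share the same
#' seed and configuration) and reports the mean silhouette and
#' Davies-Bouldin index of each partition, recommending the `k` with the
#' highest silhouette and the `k` with the lowest index.
#'
#' @param data Feature table tibble (cleaned, typically standardized).
#' @param k_values Integer vector of candidate cluster counts.
#' @param config An [aco_config()] shared across all `k`.
#' @param metric Distance metric.
#' @return A tibble of class `aco_scan` with one row per `k` (`k`,
#'   `silhouette`, `davies_bouldin`, `cost`, `converged_at`,
#'   `config_hash`), carrying `recommended_k_silhouette` and
#'   `recommended_k_db` attributes. Plot with [autoplot()].
#' @export
cluster_scan <- function(data, k_values = 2:5, config = aco_config(),
                         metric = "euclidean") {
  if (length(k_values) == 0L) abort("k_values must be non-empty")
  d <- feature_distances(data, metric)
  if (any(k_values > nrow(d))) abort("every k must be <= the number of samples")
  hash <- config_hash(config)
  rows <- purrr::map(k_values, function(k) {
    fit <- aco_cluster(data, k = k, config = config, dist = d)
    tibble::tibble(
      k = as.integer(k),
      silhouette = if (k >= 2) silhouette_score(d, fit$labels) else NA_real_,
      davies_bouldin = if (k >= 2) davies_bouldin(data, fit$labels) else NA_real_,
      cost = fit$best$cost,
      converged_at = fit$converged_at,
      config_hash = hash
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "recommended_k_silhouette") <- out$k[which.max(out$silhouette)]
  attr(out, "recommended_k_db") <- out$k[which.min(out$davies_bouldin)]
  class(out) <- c("aco_scan", class(out))
  out
}
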