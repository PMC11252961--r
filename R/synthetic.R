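#' Specify a synthetic athlete population
#'
#' Describes a mixture of athlete archetypes (endurance-dominant,
#' power-dominant, technique-dominant, ...) from which [simulate_athletes()]
#' draws a feature table with known ground truth. Each archetype is a unit
#' mean profile over the feature space; `separation` scales all profiles,
#' and samples get independent Gaussian noise with per-feature spread
#' `within_sd`.
#'
#' @param archetype_means A `k x d` numeric matrix of unit archetype
#'   profiles (rows = archetypes). Multiplied by `separation` at generation
#'   time.
#' @param n_per_cluster Integer vector of `k` per-archetype sample counts
#'   (scalars are recycled).
#' @param within_sd Positive per-feature noise standard deviation (scalars
#'   recycled to length `d`).
#' @param separation Scalar multiplier applied to the archetype means; in
#'   units of `within_sd` when `within_sd = 1`.
#' @param missing_rate Fraction of cells set missing, in `[0, 1)`. Exactly
#'   `round(missing_rate * n * d)` cells are blanked (chosen without
#'   replacement), so tests can assert the count.
#' @param duplicate_rate Fraction of rows duplicated and appended, in
#'   `[0, 1)`; `round(duplicate_rate * n)` rows are copied under fresh
#'   sample IDs.
#' @param feature_names Optional character vector of `d` feature names.
#' @param seed Integer master seed; generation is fully reproducible.
#' @return An object of class `athlete_spec`.
#' @seealso [default_athlete_spec()] for the standard block-structured
#'   profiles, [simulate_athletes()] to draw data.
#' @export
athlete_spec <- function(archetype_means,
                         n_per_cluster = 20L,
                         within_sd = 1,
                         separation = 1,
                         missing_rate = 0,
                         duplicate_rate = 0,
                         feature_names = NULL,
                         seed = 1L) {
  archetype_means <- as.matrix(archetype_means)
  k <- nrow(archetype_means)
  d <- ncol(archetype_means)
  if (k < 2L) abort("need at least 2 archetypes")
  n_per_cluster <- as.integer(rep_len(n_per_cluster, k))
  if (any(n_per_cluster < 1L)) abort("all per-archetype counts must be >= 1")
  within_sd <- rep_len(as.double(within_sd), d)
  if (any(within_sd <= 0)) abort("within_sd must be positive")
  if (missing_rate < 0 || missing_rate >= 1) abort("missing_rate must be in [0, 1)")
  if (duplicate_rate < 0 || duplicate_rate >= 1) abort("duplicate_rate must be in [0, 1)")
  if (is.null(feature_names)) feature_names <- paste0("feature_", seq_len(d))
  if (length(feature_names) != d) abort("feature_names must have one entry per column")
  colnames(archetype_means) <- feature_names
  structure(
    list(archetype_means = archetype_means, n_per_cluster = n_per_cluster,
         within_sd = within_sd, separation = as.double(separation),
         missing_rate = as.double(missing_rate),
         duplicate_rate = as.double(duplicate_rate),
         feature_names = feature_names, seed = as.integer(seed)),
    class = "athlete_spec"
  )
}

#' @export
print.athlete_spec <- function(x, ...) {
  cat(sprintf("<athlete_spec> %d archetypes x %d features, n = %s\n",
              nrow(x$archetype_means), ncol(x$archetype_means),
              paste(x$n_per_cluster, collapse = "+")))
  cat(sprintf("  separation %.3g, within_sd %.3g (mean), missing %.3g, duplicates %.3g, seed %d\n",
              x$separation, mean(x$within_sd), x$missing_rate,
              x$duplicate_rate, x$seed))
  invisible(x)
}

#' Standard athlete archetype specification
#'
#' Builds the package's standard fixture: `k` archetypes over `d` features
#' organised in four named blocks (physical, physiological, technical,
#' performance). Each archetype's unit profile is +1 on its own signature
#' group of `floor(d / k)` consecutive features and 0 elsewhere, so for
#' `k >= 3` all pairwise archetype distances are equal
#' (`separation * sqrt(2 * floor(d / k))`). For `k = 2` the two profiles
#' differ only in the first signature group (one is the zero baseline).
#'
#' With the defaults (`k = 3`, `d = 8`, 20 athletes per archetype,
#' `separation = 6`, unit noise) the ground-truth labelling has a mean
#' silhouette of about 0.68: clearly clustered but with visible overlap.
#'
#' @param k Number of archetypes (>= 2).
#' @param d Number of features (>= 4).
#' @param n_per_cluster Athletes per archetype.
#' @param separation Mean-profile scale in units of `within_sd`.
#' @param within_sd Noise standard deviation.
#' @param missing_rate,duplicate_rate,seed Passed to [athlete_spec()].
#' @return An `athlete_spec`.
#' @export
#' @examples
#' spec <- default_athlete_spec()
#' athletes <- simulate_athletes(spec)
#' dplyr::count(athletes, archetype)
default_athlete_spec <- function(k = 3L, d = 8L, n_per_cluster = 20L,
                                 separation = 6, within_sd = 1,
                                 missing_rate = 0, duplicate_rate = 0,
                                 seed = 1L) {
  if (k < 2L) abort("k must be >= 2")
  if (d < 4L) abort("d must be >= 4")
  if (d < k) abort("need at least one feature per archetype (d >= k)")
  blocks <- c("physical", "physio", "tech", "perf")
  sizes <- diff(round(seq(0, d, length.out = 5)))
  feature_names <- unlist(mapply(function(b, s) if (s > 0) paste0(b, "_", seq_len(s)) else character(),
                                 blocks, sizes, SIMPLIFY = FALSE), use.names = FALSE)
  s <- max(1L, d %/% k)
  means <- matrix(0, nrow = k, ncol = d)
  if (k == 2L) {
    means[2L, seq_len(sizes[1])] <- 1 # baseline vs elevated physical block
  } else {
    for (i in seq_len(k)) means[i, ((i - 1L) * s + 1L):(i * s)] <- 1
  }
  athlete_spec(means, n_per_cluster = n_per_cluster, within_sd = within_sd,
               separation = separation, missing_rate = missing_rate,
               duplicate_rate = duplicate_rate, feature_names = feature_names,
               seed = seed)
}

#' Simulate an athlete feature table with known archetypes
#'
#' Draws each sample from an independent Gaussian around its archetype's
#' scaled mean profile, then injects exactly `round(missing_rate * n * d)`
#' missing cells and appends `round(duplicate_rate * n)` duplicated rows.
#' Each archetype's noise substream is keyed by the archetype's own mean
#' profile and count (not its position), so permuting the archetypes in the
#' spec yields the same multiset of rows.
#'
#' @param spec An [athlete_spec()].
#' @return A tibble with `sample_id`, an `archetype` factor (the ground
#'   truth label), and one numeric column per feature.
#' @export
simulate_athletes <- function(spec) {
  stopifnot(inherits(spec, "athlete_spec"))
  k <- nrow(spec$archetype_means)
  d <- ncol(spec$archetype_means)
  counts <- spec$n_per_cluster

  blocks <- vector("list", k)
  for (i in seq_len(k)) {
    mu <- spec$separation * spec$archetype_means[i, ]
    sub <- seed_stream(spec$seed, "archetype", spec$archetype_means[i, ], counts[i])
    noise <- with_seed(sub, matrix(rnorm(counts[i] * d), nrow = counts[i]))
    blocks[[i]] <- sweep(noise, 2L, spec$within_sd, `*`) +
      matrix(mu, nrow = counts[i], ncol = d, byrow = TRUE)
  }
  values <- do.call(rbind, blocks)
  n <- nrow(values)
  labels <- factor(rep.int(seq_len(k), counts))

  n_miss <- round(spec$missing_rate * n * d)
  if (n_miss > 0) {
    cells <- with_seed(seed_stream(spec$seed, "missing"),
                       sample.int(n * d, n_miss))
    values[cells] <- NA_real_
  }

  out <- tibble::tibble(
    sample_id = sprintf("athlete_%03d", seq_len(n)),
    archetype = labels
  )
  colnames(values) <- spec$feature_names
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))

  n_dup <- round(spec$duplicate_rate * n)
  if (n_dup > 0) {
    rows <- with_seed(seed_stream(spec$seed, "duplicate"),
                      sample.int(n, n_dup, replace = TRUE))
    dup <- out[rows, , drop = FALSE]
    dup$sample_id <- sprintf("athlete_%03d_dup%d", rows, seq_len(n_dup))
    out <- dplyr::bind_rows(out, dup)
  }
  out
}
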