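# Internal helpers shared across modules.

# Deterministic 31-bit substream seed derived from a master seed plus
# arbitrary key material (numbers are keyed at 1e-6 resolution, strings by
# code point). Keeps every derived seed strictly below 2^31.
seed_stream <- function(seed, ...) {
  keys <- list(...)
  h <- as.double(seed) %% 2147483647
  for (key in keys) {
    if (is.character(key)) {
      vals <- unlist(lapply(key, utf8ToInt), use.names = FALSE)
    } else {
      vals <- round(as.double(key) * 1e6) %% 2147483647
    }
    for (v in vals) h <- (h * 31 + abs(v)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# level randomness.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Feature columns are the numeric columns; everything else (sample_id,
# label factors, other metadata) passes through untouched.
feature_cols <- function(data) {
  names(data)[vapply(data, is.numeric, logical(1))]
}

feature_matrix <- function(data) {
  cols <- feature_cols(data)
  if (length(cols) == 0L) abort("no numeric feature columns found")
  m <- as.matrix(data[cols])
  if ("sample_id" %in% names(data)) rownames(m) <- as.character(data$sample_id)
  storage.mode(m) <- "double"
  m
}

# Short stable hash of a configuration object, embedded in result tables so
# reruns can be matched to the settings that produced them.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "")
  sprintf("%08x", seed_stream(0, txt))
}

check_no_missing <- function(m, what = "data") {
  if (anyNA(m)) {
    abort(sprintf("%s contains %d missing entries; run clean_features() first",
                  what, sum(is.na(m))))
  }
  invisible(m)
}
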