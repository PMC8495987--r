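# Internal helpers shared across modules.

# Standardize a numeric vector to mean 0, SD 1 (denominator n-1).
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    abort("cannot standardize a constant (zero-variance) vector")
  }
  (x - mean(x)) / s
}

# Derive a reproducible sub-stream seed from one global seed.  Stage offsets
# keep the stream below 2^31 - 1 so it stays a valid R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    frequencies = 11L, genotypes = 23L, effects = 37L, environment = 41L,
    carriers = 53L, ascertainment = 67L, pool = 71L, clustering = 83L,
    permutation = 97L, bootstrap = 101L, trios = 113L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 127L + off * 9973) %% .Machine$integer.max)
}

check_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) abort(sprintf("`%s` must be a probability in %s", name,
                         if (open) "(0, 1)" else "[0, 1]"))
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min &&
    x == as.integer(x)
  if (!ok) abort(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

# Wilcoxon/Mann-Whitney AUC of `score` for separating status 1 from 0.
rank_auc <- function(score, status) {
  stopifnot(length(score) == length(status))
  r <- rank(score)
  n1 <- sum(status == 1)
  n0 <- sum(status == 0)
  (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
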