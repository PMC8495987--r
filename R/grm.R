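#' Empirical-Bayes cluster-specific allele frequencies
#'
#' Estimates, from an unmatched control pool, the pooled allele frequency
#' of every variant and a shrunken within-cluster frequency. Shrinkage is
#' the beta-binomial posterior mean `(c_k + m * pooled) / (2 n_k + m)`,
#' where `c_k` is the cluster allele count and the prior strength
#' `m = (1 - F) / F` comes from a Weir-Cockerham-style method-of-moments
#' estimate of the across-cluster divergence `F` (floored at `m = 20` so a
#' near-homogeneous pool still shrinks). Clusters absent from the pool fall
#' back to the pooled frequency with a warning. All frequencies are clamped
#' to `[1/(2 n_pool + 2), 1 - 1/(2 n_pool + 2)]`.
#'
#' @param genotypes `genotype_matrix` of the unmatched control pool.
#' @param clusters Factor of cluster labels for the pool subjects.
#' @param prior_m Optional fixed prior strength (allele-count units),
#'   bypassing the method-of-moments estimate.
#' @return A `freq_estimates` object: `pooled` (per variant), `raw` and
#'   `eb` (variant x cluster matrices), cluster sizes `n_k`, prior strength
#'   `prior_m`, divergence estimate `fhat`, and a `monomorphic` flag for
#'   variants with no variation in the pool.
#' @export
estimate_frequencies <- function(genotypes, clusters, prior_m = NULL) {
  if (nrow(genotypes) == 0) abort("control pool is empty")
  clusters <- as.factor(clusters)
  stopifnot(length(clusters) == nrow(genotypes))
  x <- unclass(genotypes)
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    abort(paste("variants missing in all pool subjects:",
                paste(head(variants(genotypes)$variant_id[all_missing], 5),
                      collapse = ", ")))
  }
  n_pool <- nrow(x)
  lo <- 1 / (2 * n_pool + 2)
  clamp <- function(p) pmin(pmax(p, lo), 1 - lo)

  pooled_raw <- colMeans(x, na.rm = TRUE) / 2
  monomorphic <- pooled_raw <= 0 | pooled_raw >= 1
  pooled <- clamp(pooled_raw)

  lev <- levels(clusters)
  n_k <- vapply(lev, function(l) sum(clusters == l), integer(1))
  counts <- vapply(lev, function(l) {
    colSums(x[clusters == l, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(x)))
  nonmiss <- vapply(lev, function(l) {
    colSums(!is.na(x[clusters == l, , drop = FALSE]))
  }, numeric(ncol(x)))
  dim(counts) <- dim(nonmiss) <- c(ncol(x), length(lev))
  colnames(counts) <- colnames(nonmiss) <- lev
  raw <- counts / pmax(1, 2 * nonmiss)
  empty <- n_k == 0
  if (any(empty)) {
    warn(paste("clusters absent from pool fall back to pooled frequency:",
               paste(lev[empty], collapse = ", ")))
    raw[, empty] <- pooled
  }

  # method-of-moments divergence: weighted across-cluster variance of raw
  # frequencies, corrected for binomial sampling noise
  wk <- n_k / sum(n_k)
  poly <- !monomorphic
  pbar <- pooled_raw[poly]
  vv <- rowSums(sweep((raw[poly, !empty, drop = FALSE] - pbar)^2, 2,
                      wk[!empty], `*`))
  sampling <- pbar * (1 - pbar) * sum(wk[!empty] / (2 * n_k[!empty])) /
    sum(wk[!empty])
  denom <- sum(pbar * (1 - pbar))
  fhat <- if (denom > 0) sum(vv - sampling) / denom else 0
  fhat <- min(max(fhat, 1e-6), 0.5)
  if (is.null(prior_m)) prior_m <- max(20, (1 - fhat) / fhat)

  eb <- raw
  for (k in seq_along(lev)) {
    if (empty[k]) next
    eb[, k] <- (counts[, k] + prior_m * pooled) / (2 * nonmiss[, k] + prior_m)
  }
  eb <- clamp(eb)

  structure(
    list(
      variant_id = variants(genotypes)$variant_id,
      pooled = pooled, raw = raw, eb = eb,
      clusters = lev, n_k = n_k, n_pool = n_pool,
      prior_m = prior_m, fhat = fhat, monomorphic = monomorphic
    ),
    class = "freq_estimates"
  )
}

#' @export
print.freq_estimates <- function(x, ...) {
  cat(sprintf("<freq_estimates: %d variants, %d clusters (pool n = %d); prior strength m = %.1f (F-hat = %.4g); %d monomorphic>\n",
              length(x$pooled), length(x$clusters), x$n_pool, x$prior_m,
              x$fhat, sum(x$monomorphic)))
  invisible(x)
}

#' @rdname estimate_frequencies
#' @param x A `freq_estimates`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.freq_estimates <- function(x, ...) {
  base <- tibble(variant_id = x$variant_id, pooled = x$pooled,
                 monomorphic = x$monomorphic)
  long <- purrr::map(seq_along(x$clusters), function(k) {
    tibble(variant_id = x$variant_id, cluster = x$clusters[k],
           raw = x$raw[, k], eb = x$eb[, k], n = x$n_k[k])
  }) |> list_rbind()
  left_join(long, base, by = "variant_id")
}

#' Standardize genotypes by cluster-specific or pooled frequencies
#'
#' Each dosage becomes `(x - 2p) / sqrt(2 p (1 - p))` with `p` the
#' empirical-Bayes cluster frequency of the subject's own cluster
#' (`mode = "CLS"`) or the pooled frequency (`mode = "POP"`). Missing
#' dosages are imputed to `2p` (0 after standardization).
#'
#' @param genotypes A `genotype_matrix`.
#' @param frequencies A `freq_estimates` from [estimate_frequencies()].
#' @param mode `"CLS"` or `"POP"`.
#' @param clusters Factor of cluster labels for the rows of `genotypes`
#'   (required for CLS); levels must match those used in
#'   [estimate_frequencies()].
#' @return Numeric matrix of standardized dosages (same dimensions).
#' @export
standardize_genotypes <- function(genotypes, frequencies,
                                  mode = c("CLS", "POP"), clusters = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(frequencies, "freq_estimates"))
  x <- unclass(genotypes)
  storage.mode(x) <- "double"
  if (mode == "POP") {
    p <- matrix(frequencies$pooled, nrow(x), ncol(x), byrow = TRUE)
  } else {
    if (is.null(clusters)) abort("CLS standardization requires `clusters`")
    clusters <- as.factor(clusters)
    stopifnot(length(clusters) == nrow(x))
    ki <- match(as.character(clusters), frequencies$clusters)
    if (anyNA(ki)) abort("cluster labels not present in frequency estimates")
    p <- t(frequencies$eb[, ki, drop = FALSE])
  }
  stopifnot(all(p > 0 & p < 1))
  z <- (x - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(x)] <- 0
  dimnames(z) <- dimnames(x)
  z
}

new_grm <- function(matrix, ids, mode, m_variants) {
  dimnames(matrix) <- list(ids, ids)
  structure(list(matrix = matrix, ids = ids, mode = mode,
                 m_variants = m_variants),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("<grm: %d subjects, mode %s, %d variants>\n",
              length(x$ids), x$mode, x$m_variants))
  invisible(x)
}

#' Genomic relationship matrix
#'
#' Builds one of three GRM variants. `CLS` and `POP` standardize genotypes
#' with [standardize_genotypes()] (empirical-Bayes cluster frequencies and
#' pooled-control frequencies respectively) and form `Z Z' / M`. `STD` is
#' the tool-default estimator computed from all-sample allele frequencies:
#' off-diagonals are `sum_i (x_ij - 2p_i)(x_ik - 2p_i) / (2 p_i (1 - p_i)) / M`
#' and diagonals are `1 + sum_i (x_j^2 - (1 + 2p_i) x_j + 2 p_i^2) /
#' (2 p_i (1 - p_i)) / M`. Variants monomorphic in the frequency source are
#' excluded with a message.
#'
#' @param genotypes A `genotype_matrix` of the analysis subjects.
#' @param mode `"CLS"`, `"POP"` or `"STD"`.
#' @param frequencies `freq_estimates` (required for CLS/POP).
#' @param clusters Cluster labels of the analysis subjects (CLS only).
#' @return A `grm` object.
#' @export
compute_grm <- function(genotypes, mode = c("CLS", "POP", "STD"),
                        frequencies = NULL, clusters = NULL) {
  mode <- match.arg(mode)
  if (nrow(genotypes) < 2) abort("need at least 2 subjects")
  ids <- rownames(genotypes)

  if (mode == "STD") {
    x <- unclass(genotypes)
    storage.mode(x) <- "double"
    p <- colMeans(x, na.rm = TRUE) / 2
    v <- colMeans(x^2, na.rm = TRUE) - colMeans(x, na.rm = TRUE)^2
    usable <- p > 0 & p < 1 & v > 0
    if (sum(usable) == 0) abort("zero usable (polymorphic) variants")
    if (any(!usable)) {
      inform(sprintf("excluding %d monomorphic variants from STD GRM",
                     sum(!usable)))
    }
    x <- x[, usable, drop = FALSE]
    p <- p[usable]
    m <- ncol(x)
    denom <- 2 * p * (1 - p)
    xm <- sweep(x, 2, 2 * p)
    xm[is.na(xm)] <- 0
    z <- sweep(xm, 2, sqrt(denom), `/`)
    a <- tcrossprod(z) / m
    # tool-default diagonal
    x0 <- x
    x0[is.na(x0)] <- rep(2 * p, each = nrow(x))[is.na(x0)]
    dterm <- sweep(x0^2 - sweep(x0, 2, 1 + 2 * p, `*`), 2, 2 * p^2, `+`)
    diag_vals <- 1 + rowSums(sweep(dterm, 2, denom, `/`)) / m
    diag(a) <- diag_vals
    return(new_grm(a, ids, "STD", m))
  }

  if (is.null(frequencies)) abort("CLS/POP GRMs require `frequencies`")
  usable <- !frequencies$monomorphic
  if (sum(usable) == 0) abort("zero usable (polymorphic) variants")
  if (any(!usable)) {
    inform(sprintf("excluding %d variants monomorphic in the pool", sum(!usable)))
  }
  v <- variants(genotypes)
  sub <- new_genotype_matrix(unclass(genotypes)[, usable, drop = FALSE],
                             ids, v[usable, ])
  fsub <- frequencies
  fsub$pooled <- fsub$pooled[usable]
  fsub$raw <- fsub$raw[usable, , drop = FALSE]
  fsub$eb <- fsub$eb[usable, , drop = FALSE]
  fsub$variant_id <- fsub$variant_id[usable]
  fsub$monomorphic <- fsub$monomorphic[usable]
  z <- standardize_genotypes(sub, fsub, mode, clusters)
  a <- tcrossprod(z) / ncol(z)
  new_grm(a, ids, mode, ncol(z))
}

#' @rdname compute_grm
#' @param x A `grm`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.grm <- function(x, ...) {
  idx <- which(upper.tri(x$matrix, diag = TRUE), arr.ind = TRUE)
  tibble(id1 = x$ids[idx[, 1]], id2 = x$ids[idx[, 2]],
         value = x$matrix[idx], mode = x$mode)
}
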