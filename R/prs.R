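#' Align GWAS summary statistics to a genotype file's counted allele
#'
#' Matches summary statistics to genotyped variants by id and orients the
#' effect sizes to the dosage-counted allele (`a1`): effects are kept when
#' the effect allele equals `a1`, sign-flipped when the alleles are
#' swapped, and the variant is dropped when the allele pair does not match.
#' Strand-ambiguous variants (A/T, C/G) are dropped when `drop_ambiguous`.
#' Counts of dropped variants are reported via a message.
#'
#' @param stats Tibble with `variant_id`, `effect_allele`, `other_allele`,
#'   `effect` (log-odds) and `p`.
#' @param genotypes A `genotype_matrix` whose variant table carries the
#'   counted allele `a1` and other allele `a2`.
#' @param drop_ambiguous Drop strand-ambiguous variants? Default TRUE.
#' @return The aligned stats tibble (effects oriented to `a1`), with
#'   attribute `dropped` recording the counts.
#' @export
align_alleles <- function(stats, genotypes, drop_ambiguous = TRUE) {
  stats <- as_tibble(stats)
  need <- c("variant_id", "effect_allele", "other_allele", "effect", "p")
  stopifnot(all(need %in% names(stats)))
  v <- variants(genotypes)
  m <- left_join(stats, v[, c("variant_id", "a1", "a2")], by = "variant_id")
  unmatched <- is.na(m$a1)
  ambiguous <- !unmatched & drop_ambiguous &
    paste0(pmin(m$effect_allele, m$other_allele),
           pmax(m$effect_allele, m$other_allele)) %in% c("AT", "CG")
  same <- m$effect_allele == m$a1 & m$other_allele == m$a2
  swapped <- m$effect_allele == m$a2 & m$other_allele == m$a1
  mismatch <- !unmatched & !ambiguous & !(same | swapped)
  keep <- !unmatched & !ambiguous & !mismatch
  if (sum(keep) == 0) abort("zero variants overlap between stats and genotypes")
  inform(sprintf(
    "align_alleles: kept %d (%d flipped); dropped %d unmatched, %d ambiguous, %d allele-mismatched",
    sum(keep), sum(swapped & keep), sum(unmatched), sum(ambiguous),
    sum(mismatch)))
  out <- m[keep, ]
  out$effect <- ifelse(swapped[keep], -out$effect, out$effect)
  out <- out |>
    mutate(effect_allele = .data$a1, other_allele = .data$a2) |>
    select(dplyr::all_of(need))
  attr(out, "dropped") <- c(unmatched = sum(unmatched),
                            ambiguous = sum(ambiguous),
                            mismatch = sum(mismatch))
  out
}

#' Greedy LD clumping of summary statistics
#'
#' Sorts variants by ascending p-value; repeatedly takes the best remaining
#' variant as an index and removes every variant within
#' `clump_window_kb` kilobases having squared dosage correlation above
#' `clump_r2` with it in the LD reference; finally returns the index
#' variants with `p < p_threshold`.
#'
#' @param stats Aligned summary statistics (see [align_alleles()]).
#' @param genotypes LD-reference `genotype_matrix` (conventionally the
#'   unmatched-control pool, keeping the analysis sample untouched).
#' @param clump_r2 r-squared threshold (default 0.1).
#' @param clump_window_kb Window in kb (default 250).
#' @param p_threshold Inclusion p-value threshold (default 0.01).
#' @return Character vector of retained index variant ids.
#' @export
clump <- function(stats, genotypes, clump_r2 = 0.1, clump_window_kb = 250,
                  p_threshold = 0.01) {
  check_prob(p_threshold, "p_threshold", open = FALSE)
  stats <- as_tibble(stats)
  v <- variants(genotypes)
  m <- left_join(stats, v[, c("variant_id", "chr", "pos")], by = "variant_id")
  m <- m[!is.na(m$pos), ]
  m <- m[order(m$p, m$variant_id), ]
  x <- unclass(genotypes)[, match(m$variant_id, v$variant_id), drop = FALSE]
  alive <- rep(TRUE, nrow(m))
  index <- character(0)
  for (i in seq_len(nrow(m))) {
    if (!alive[i]) next
    index <- c(index, m$variant_id[i])
    near <- which(alive & m$chr == m$chr[i] &
                    abs(m$pos - m$pos[i]) <= clump_window_kb * 1000)
    near <- setdiff(near, i)
    if (length(near) > 0) {
      r2 <- suppressWarnings(
        cor(x[, i], x[, near, drop = FALSE])
      )^2
      r2[!is.finite(r2)] <- 0
      alive[near[r2 > clump_r2]] <- FALSE
    }
    alive[i] <- FALSE
  }
  ps <- m$p[match(index, m$variant_id)]
  out <- index[ps < p_threshold]
  if (length(out) == 0) warn("clumping retained no variants below p_threshold")
  out
}

#' Polygenic risk score from aligned summary statistics
#'
#' Per subject, the sum of aligned effect sizes times dosages over the
#' index variant set; missing dosages are mean-imputed per variant. The
#' score is standardized to mean 0, SD 1 over the scored subjects.
#'
#' @param genotypes A `genotype_matrix` of the subjects to score.
#' @param stats Aligned summary statistics.
#' @param index Character vector of index variant ids (e.g. from
#'   [clump()]).
#' @param name Score label (default "PRS").
#' @return A `score_vector` tibble: `subject_id`, `score`, `raw`.
#' @export
prs_score <- function(genotypes, stats, index, name = "PRS") {
  if (length(index) == 0) abort("index variant set is empty")
  v <- variants(genotypes)
  stats <- as_tibble(stats)
  idx <- match(index, v$variant_id)
  if (anyNA(idx)) abort("index variants missing from genotypes")
  eff <- stats$effect[match(index, stats$variant_id)]
  if (anyNA(eff)) abort("index variants missing from stats")
  x <- unclass(genotypes)[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    nas <- which(is.na(x), arr.ind = TRUE)
    x[nas] <- mu[nas[, 2]]
  }
  raw <- unname(drop(x %*% eff))
  score <- if (stats::sd(raw) > 0) standardize(raw) else raw
  new_score(tibble(subject_id = rownames(genotypes), score = score, raw = raw),
            name = name,
            provenance = sprintf("P+T score over %d variants", length(index)),
            standardized = stats::sd(raw) > 0)
}

#' Simulate GWAS summary statistics from a training cohort
#'
#' Per-variant logistic (score-test style) association of case status with
#' dosage in a simulated training cohort, yielding effect sizes and
#' p-values in the standard summary-statistics layout. Used to exercise the
#' P+T machinery end-to-end without external GWAS data.
#'
#' @param genotypes Training `genotype_matrix`.
#' @param status 0/1 phenotype for its rows.
#' @return Summary-statistics tibble suitable for [align_alleles()].
#' @export
simulate_summary_stats <- function(genotypes, status) {
  x <- unclass(genotypes)
  storage.mode(x) <- "double"
  v <- variants(genotypes)
  y <- as.numeric(status)
  yc <- y - mean(y)
  n <- length(y)
  # per-variant linear association on the observed scale; beta / se via the
  # usual single-regressor identities, converted to the logistic scale by
  # the variance factor 1 / (ybar (1 - ybar))
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  sxx <- colSums(xc^2)
  sxx[sxx == 0] <- NA
  beta_lin <- colSums(xc * yc) / sxx
  res_var <- pmax(1e-12,
                  (sum(yc^2) - beta_lin^2 * sxx) / (n - 2))
  se_lin <- sqrt(res_var / sxx)
  z <- beta_lin / se_lin
  pbar <- mean(y)
  scale <- 1 / (pbar * (1 - pbar))
  tibble(
    variant_id = v$variant_id,
    effect_allele = v$a1,
    other_allele = v$a2,
    effect = ifelse(is.na(beta_lin), 0, beta_lin * scale),
    p = ifelse(is.na(z), 1, 2 * pnorm(-abs(z)))
  )
}
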