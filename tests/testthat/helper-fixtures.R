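# Shared fixture builders. Everything is generated in code at test time.

# A tiny genotype_matrix from an explicit dosage matrix.
toy_genotypes <- function(x, ids = NULL, pos = NULL, a1 = "A", a2 = "G") {
  x <- as.matrix(x)
  ids <- ids %||% sprintf("s%02d", seq_len(nrow(x)))
  m <- ncol(x)
  vt <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_len(m)), chr = 1L,
    pos = pos %||% seq_len(m),
    a1 = rep(a1, length.out = m), a2 = rep(a2, length.out = m)
  )
  polyrisk:::new_genotype_matrix(x, ids, vt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a cohort's genotype matrix by subject ids.
geno_subset <- function(cohort, ids) {
  polyrisk:::new_genotype_matrix(
    unclass(cohort$genotypes)[match(ids, rownames(cohort$genotypes)), ,
                              drop = FALSE],
    ids, variants(cohort$genotypes))
}

# Run the cohort through ancestry + CLS-GRM + leave-pair-out GP; the
# standard analysis head shared by several simulation-based tests.
run_gp_analysis <- function(cohort, k = cohort$config$k_clusters, d = 3,
                            h2 = 0.70, prune = FALSE) {
  geno <- cohort$genotypes
  pruned <- if (prune) ld_prune(geno) else NULL
  space <- compute_eigenvectors(geno, pruned, d = d)
  space <- cluster_subjects(space, k = k, seed = cohort$config$seed)
  subj <- cohort$subjects
  analysis <- subj[subj$cohort != "pool_control", c("subject_id", "status")]
  pairs <- match_pairs(space, analysis)
  pool_ids <- subj$subject_id[subj$cohort == "pool_control"]
  pool_geno <- geno_subset(cohort, pool_ids)
  freqs <- estimate_frequencies(pool_geno,
                                space$clusters[match(pool_ids, space$ids)])
  an_geno <- geno_subset(cohort, analysis$subject_id)
  grm <- compute_grm(an_geno, "CLS", freqs,
                     clusters = space$clusters[match(analysis$subject_id,
                                                     space$ids)])
  gp <- leave_pair_out_gp(grm, pairs, subj, h2 = h2)
  list(space = space, pairs = pairs, freqs = freqs, grm = grm, gp = gp,
       analysis = analysis)
}

# Adjusted Rand index between two label vectors (independent implementation
# for clustering checks).
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
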