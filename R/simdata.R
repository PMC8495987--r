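#' Configuration for the structured-population cohort simulator
#'
#' Collects the parameters of the generative model used throughout the
#' package's validation machinery: `k_clusters` ancestry clusters whose
#' allele frequencies diverge from a shared ancestral frequency under the
#' Balding-Nichols model with divergence `fst`; an additive polygenic
#' liability built from `m_causal` causal variants with heritability `h2`;
#' binary diagnosis by thresholding liability at the quantile implied by
#' `prevalence`; rare damaging-variant (PDV) carriers at rate `pdv_rate`
#' whose liability is shifted by `pdv_shift`; and case ascertainment with
#' genetically matched controls plus an extra unmatched-control pool used
#' only for allele-frequency estimation.
#'
#' @param n_cases Number of ascertained cases.
#' @param n_matched_controls Number of controls drawn to mirror the cases'
#'   cluster composition (defaults to `n_cases`).
#' @param n_pool_controls Size of the unmatched control pool used for
#'   allele-frequency estimation.
#' @param k_clusters Number of ancestry clusters.
#' @param cluster_weights Sampling probabilities over clusters; must sum
#'   to 1. Defaults to equal weights.
#' @param fst Balding-Nichols divergence in (0, 1); scalar or one value per
#'   cluster. Default 0.01, continental-scale European substructure.
#' @param m_snps Number of variants.
#' @param m_causal Number of causal variants; defaults to `m_snps`
#'   (infinitesimal architecture, matching the G-BLUP working model).
#' @param h2 Heritability of liability attributable to common variants.
#'   Default 0.70.
#' @param prevalence Population prevalence of diagnosis. Default 0.015.
#' @param pdv_rate Probability any subject carries a PDV. Default 0.02.
#' @param pdv_shift Liability shift per carrier. Defaults to
#'   `carrier_shift(prevalence, 15, "odds_ratio")`, i.e. the shift implied
#'   by a 15-fold excess disease odds.
#' @param seed Integer seed; all stage-specific random streams are derived
#'   from it deterministically.
#' @param world_seed Seed for the shared "world" (allele frequencies and
#'   causal effects). Defaults to `seed`; give two configs the same
#'   `world_seed` and different `seed`s to draw independent cohorts of the
#'   same trait, e.g. a GWAS training cohort and a target cohort.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cases = 500,
                       n_matched_controls = n_cases,
                       n_pool_controls = 1000,
                       k_clusters = 4,
                       cluster_weights = rep(1 / k_clusters, k_clusters),
                       fst = 0.01,
                       m_snps = 5000,
                       m_causal = m_snps,
                       h2 = 0.70,
                       prevalence = 0.015,
                       pdv_rate = 0.02,
                       pdv_shift = NULL,
                       seed = 1L,
                       world_seed = seed) {
  n_cases <- check_count(n_cases, "n_cases")
  n_matched_controls <- check_count(n_matched_controls, "n_matched_controls", 0)
  n_pool_controls <- check_count(n_pool_controls, "n_pool_controls", 0)
  k_clusters <- check_count(k_clusters, "k_clusters")
  m_snps <- check_count(m_snps, "m_snps")
  m_causal <- check_count(m_causal, "m_causal", 0)
  if (m_causal > m_snps) abort("`m_causal` must be <= `m_snps`")
  if (length(cluster_weights) != k_clusters ||
      any(cluster_weights < 0) || abs(sum(cluster_weights) - 1) > 1e-8) {
    abort("`cluster_weights` must be a probability simplex over clusters")
  }
  if (any(fst <= 0 | fst >= 1)) abort("`fst` must lie in (0, 1)")
  if (!(length(fst) %in% c(1, k_clusters))) {
    abort("`fst` must be scalar or one value per cluster")
  }
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) abort("`h2` must lie in [0, 1]")
  check_prob(prevalence, "prevalence")
  check_prob(pdv_rate, "pdv_rate", open = FALSE)
  if (is.null(pdv_shift)) {
    pdv_shift <- carrier_shift(prevalence, 15, "odds_ratio")
  }
  structure(
    list(
      n_cases = n_cases, n_matched_controls = n_matched_controls,
      n_pool_controls = n_pool_controls, k_clusters = k_clusters,
      cluster_weights = cluster_weights, fst = rep(fst, length.out = k_clusters),
      m_snps = m_snps, m_causal = m_causal, h2 = h2,
      prevalence = prevalence, pdv_rate = pdv_rate, pdv_shift = pdv_shift,
      seed = as.integer(seed), world_seed = as.integer(world_seed)
    ),
    class = "sim_config"
  )
}

#' Balding-Nichols structured allele frequencies
#'
#' Draws ancestral allele frequencies uniform on `[0.05, 0.95]` and, for
#' each cluster, frequencies from the Balding-Nichols beta distribution
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`.
#'
#' @param m_snps Number of variants.
#' @param k_clusters Number of clusters.
#' @param fst Divergence parameter in (0, 1); scalar or per cluster.
#' @param seed Integer seed.
#' @return A list with `ancestral` (length `m_snps`) and `cluster`
#'   (`m_snps` x `k_clusters` matrix); all frequencies in (0, 1).
#' @export
draw_structured_frequencies <- function(m_snps, k_clusters, fst, seed = 1L) {
  m_snps <- check_count(m_snps, "m_snps")
  k_clusters <- check_count(k_clusters, "k_clusters")
  if (any(fst <= 0 | fst >= 1)) abort("`fst` must lie in (0, 1)")
  fst <- rep(fst, length.out = k_clusters)
  set.seed(seed)
  p <- runif(m_snps, 0.05, 0.95)
  cl <- vapply(seq_len(k_clusters), function(k) {
    f <- fst[k]
    q <- rbeta(m_snps, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    pmin(pmax(q, 1e-6), 1 - 1e-6)
  }, numeric(m_snps))
  colnames(cl) <- paste0("cluster", seq_len(k_clusters))
  list(ancestral = p, cluster = cl)
}

# Simulate one chunk of subjects: genotypes, polygenic score, liability,
# case status. Shared by simulate_population() and simulate_cohort().
# freq: output of draw_structured_frequencies; beta: per-variant effects on
# the standardized-genotype scale (0 for non-causal variants).
sim_chunk <- function(n, cfg, freq, beta, causal) {
  k <- cfg$k_clusters
  cl <- sample.int(k, n, replace = TRUE, prob = cfg$cluster_weights)
  m <- cfg$m_snps
  # genotypes: n x m, Binomial(2, cluster frequency)
  pmat <- t(freq$cluster[, cl, drop = FALSE])       # n x m
  x <- matrix(rbinom(n * m, 2L, pmat), nrow = n, ncol = m)
  # polygenic score from causal variants, standardized within own cluster
  if (length(causal) > 0 && cfg$h2 > 0) {
    pc <- pmat[, causal, drop = FALSE]
    z <- (x[, causal, drop = FALSE] - 2 * pc) / sqrt(2 * pc * (1 - pc))
    g <- drop(z %*% beta[causal])
  } else {
    g <- numeric(n)
  }
  carrier <- runif(n) < cfg$pdv_rate
  env_sd <- sqrt(max(0, 1 - cfg$h2))
  liab <- g + cfg$pdv_shift * carrier + rnorm(n, 0, env_sd)
  thr <- threshold_from_prevalence(cfg$prevalence)
  list(
    genotypes = x, cluster = cl, polygenic = g, carrier = carrier,
    liability = liab, status = as.integer(liab > thr)
  )
}

sim_effects <- function(cfg) {
  set.seed(derive_seed(cfg$world_seed %||% cfg$seed, "effects"))
  causal <- sort(sample.int(cfg$m_snps, cfg$m_causal))
  beta <- numeric(cfg$m_snps)
  if (cfg$m_causal > 0) {
    beta[causal] <- rnorm(cfg$m_causal, 0, sqrt(cfg$h2 / max(1, cfg$m_causal)))
  }
  list(causal = causal, beta = beta)
}

variant_table <- function(m) {
  tibble(
    variant_id = paste0("sim", seq_len(m)), chr = 1L, pos = seq_len(m),
    a1 = "A", a2 = "B"
  )
}

new_genotype_matrix <- function(x, ids, variants) {
  storage.mode(x) <- "integer"
  rownames(x) <- ids
  colnames(x) <- variants$variant_id
  structure(x, variants = variants, class = c("genotype_matrix", "matrix", "array"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d subjects x %d variants>\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Variant metadata of a genotype matrix
#' @param genotypes A `genotype_matrix`.
#' @return Tibble with `variant_id`, `chr`, `pos`, `a1`, `a2`.
#' @export
variants <- function(genotypes) {
  attr(genotypes, "variants") %||%
    variant_table(ncol(genotypes))
}

#' Simulate an unascertained population sample
#'
#' Draws `n` subjects from the generative model of [sim_config()] without
#' any case ascertainment: cluster labels, Binomial(2, cluster-frequency)
#' genotypes, additive polygenic liability, PDV carrier flags, and binary
#' status from the liability threshold.
#'
#' @param config A [sim_config()].
#' @param n Number of subjects.
#' @return A list of class `sim_population` with `genotypes`
#'   (a `genotype_matrix`) and `subjects` (tibble: `subject_id`, `cluster`,
#'   `carrier_flag`, `true_polygenic`, `true_liability`, `status`).
#' @export
simulate_population <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  n <- check_count(n, "n")
  freq <- draw_structured_frequencies(config$m_snps, config$k_clusters,
                                      config$fst,
                                      derive_seed(config$world_seed %||% config$seed,
                                                  "frequencies"))
  eff <- sim_effects(config)
  set.seed(derive_seed(config$seed, "genotypes"))
  ch <- sim_chunk(n, config, freq, eff$beta, eff$causal)
  ids <- sprintf("pop%06d", seq_len(n))
  subjects <- tibble(
    subject_id = ids,
    cluster = factor(paste0("C", ch$cluster)),
    carrier_flag = ch$carrier,
    true_polygenic = ch$polygenic,
    true_liability = ch$liability,
    status = ch$status
  )
  structure(
    list(
      genotypes = new_genotype_matrix(ch$genotypes, ids,
                                      variant_table(config$m_snps)),
      subjects = subjects,
      frequencies = freq,
      effects = tibble(variant_id = paste0("sim", eff$causal),
                       effect = eff$beta[eff$causal]),
      config = config
    ),
    class = "sim_population"
  )
}

#' Simulate an ascertained case-control cohort
#'
#' Runs the generative model of [sim_config()] with rejection sampling
#' until `n_cases` affected subjects are found (hard cap 1e7 draws), then
#' draws matched controls mirroring the cases' cluster composition and an
#' unmatched control pool used for allele-frequency estimation.
#'
#' @param config A [sim_config()].
#' @param max_draws Rejection-sampling cap (default 1e7 population draws).
#' @return A list of class `sim_cohort` with elements `genotypes` (cases,
#'   matched controls, then pool controls), `subjects` (tibble:
#'   `subject_id`, `cohort` in case/matched_control/pool_control, `status`,
#'   `cluster`, `carrier_flag`), `truth` (tibble with `true_polygenic`,
#'   `true_liability` per subject), `frequencies`, `effects`, `config`.
#' @export
simulate_cohort <- function(config, max_draws = 1e7) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  freq <- draw_structured_frequencies(cfg$m_snps, cfg$k_clusters, cfg$fst,
                                      derive_seed(cfg$world_seed %||% cfg$seed,
                                                  "frequencies"))
  eff <- sim_effects(cfg)
  set.seed(derive_seed(cfg$seed, "ascertainment"))

  chunk_n <- 2000L
  cap <- max_draws
  drawn <- 0
  cases <- list()
  n_cases_have <- 0
  # unaffected reservoir caps: cluster composition of the unaffected matches
  # cluster_weights closely, so 4x the total demand is ample
  demand <- cfg$n_matched_controls + cfg$n_pool_controls
  cap_k <- pmax(25L, ceiling(4 * demand * cfg$cluster_weights))
  reservoir <- vector("list", cfg$k_clusters)
  res_n <- integer(cfg$k_clusters)

  while (n_cases_have < cfg$n_cases) {
    if (drawn >= cap) {
      abort(sprintf(
        "ascertainment infeasible: %d cases found in %d draws (prevalence %.4g)",
        n_cases_have, drawn, cfg$prevalence))
    }
    ch <- sim_chunk(chunk_n, cfg, freq, eff$beta, eff$causal)
    drawn <- drawn + chunk_n
    aff <- which(ch$status == 1L)
    if (length(aff) > 0) {
      take <- aff[seq_len(min(length(aff), cfg$n_cases - n_cases_have))]
      cases[[length(cases) + 1]] <- lapply(
        list(genotypes = ch$genotypes[take, , drop = FALSE],
             cluster = ch$cluster[take], polygenic = ch$polygenic[take],
             carrier = ch$carrier[take], liability = ch$liability[take]),
        identity)
      n_cases_have <- n_cases_have + length(take)
    }
    una <- which(ch$status == 0L)
    for (k in seq_len(cfg$k_clusters)) {
      need <- cap_k[k] - res_n[k]
      if (need <= 0) next
      uk <- una[ch$cluster[una] == k]
      uk <- uk[seq_len(min(length(uk), need))]
      if (length(uk) == 0) next
      reservoir[[k]] <- c(reservoir[[k]], list(list(
        genotypes = ch$genotypes[uk, , drop = FALSE],
        polygenic = ch$polygenic[uk], carrier = ch$carrier[uk],
        liability = ch$liability[uk])))
      res_n[k] <- res_n[k] + length(uk)
    }
  }

  bindf <- function(lst, field) do.call(rbind, lapply(lst, `[[`, field))
  bindv <- function(lst, field) do.call(c, lapply(lst, `[[`, field))
  case_g <- bindf(cases, "genotypes")
  case_cl <- bindv(cases, "cluster")
  case_poly <- bindv(cases, "polygenic")
  case_carrier <- bindv(cases, "carrier")
  case_liab <- bindv(cases, "liability")

  res_flat <- lapply(seq_len(cfg$k_clusters), function(k) {
    if (res_n[k] == 0) return(NULL)
    list(genotypes = bindf(reservoir[[k]], "genotypes"),
         polygenic = bindv(reservoir[[k]], "polygenic"),
         carrier = bindv(reservoir[[k]], "carrier"),
         liability = bindv(reservoir[[k]], "liability"))
  })

  # matched controls: mirror the cases' cluster composition
  case_comp <- tabulate(case_cl, nbins = cfg$k_clusters)
  want_k <- round(case_comp * cfg$n_matched_controls / sum(case_comp))
  taken <- integer(cfg$k_clusters)
  mc <- list()
  for (k in seq_len(cfg$k_clusters)) {
    if (want_k[k] == 0) next
    if (is.null(res_flat[[k]]) || res_n[k] < want_k[k]) {
      abort(sprintf("cluster %d: %d matched controls requested but only %d unaffected available",
                    k, want_k[k], res_n[k]))
    }
    idx <- seq_len(want_k[k])
    mc[[length(mc) + 1]] <- list(
      genotypes = res_flat[[k]]$genotypes[idx, , drop = FALSE],
      cluster = rep(k, want_k[k]),
      polygenic = res_flat[[k]]$polygenic[idx],
      carrier = res_flat[[k]]$carrier[idx],
      liability = res_flat[[k]]$liability[idx])
    taken[k] <- want_k[k]
  }

  # pool controls: unaffected, drawn irrespective of matching (cluster
  # composition follows the population weights)
  pool_k <- as.vector(stats::rmultinom(1, cfg$n_pool_controls,
                                       cfg$cluster_weights))
  pc <- list()
  for (k in seq_len(cfg$k_clusters)) {
    if (pool_k[k] == 0) next
    avail <- res_n[k] - taken[k]
    if (avail < pool_k[k]) {
      abort(sprintf("cluster %d: pool demands %d unaffected, only %d left",
                    k, pool_k[k], avail))
    }
    idx <- taken[k] + seq_len(pool_k[k])
    pc[[length(pc) + 1]] <- list(
      genotypes = res_flat[[k]]$genotypes[idx, , drop = FALSE],
      cluster = rep(k, pool_k[k]),
      polygenic = res_flat[[k]]$polygenic[idx],
      carrier = res_flat[[k]]$carrier[idx],
      liability = res_flat[[k]]$liability[idx])
  }

  geno <- rbind(case_g, bindf(mc, "genotypes"), bindf(pc, "genotypes"))
  n_mc <- sum(vapply(mc, function(x) length(x$cluster), integer(1)))
  n_pc <- sum(vapply(pc, function(x) length(x$cluster), integer(1)))
  ids <- c(sprintf("case%05d", seq_len(nrow(case_g))),
           sprintf("ctrl%05d", seq_len(n_mc)),
           sprintf("pool%05d", seq_len(n_pc)))
  cohort <- c(rep("case", nrow(case_g)), rep("matched_control", n_mc),
              rep("pool_control", n_pc))
  cl_all <- c(case_cl, bindv(mc, "cluster"), bindv(pc, "cluster"))
  poly_all <- c(case_poly, bindv(mc, "polygenic"), bindv(pc, "polygenic"))
  carrier_all <- c(case_carrier, bindv(mc, "carrier"), bindv(pc, "carrier"))
  liab_all <- c(case_liab, bindv(mc, "liability"), bindv(pc, "liability"))

  subjects <- tibble(
    subject_id = ids, cohort = cohort,
    status = as.integer(cohort == "case"),
    cluster = factor(paste0("C", cl_all)),
    carrier_flag = carrier_all
  )
  truth <- tibble(
    subject_id = ids, cluster = subjects$cluster,
    carrier_flag = carrier_all,
    true_polygenic = poly_all, true_liability = liab_all
  )
  structure(
    list(
      genotypes = new_genotype_matrix(geno, ids, variant_table(cfg$m_snps)),
      subjects = subjects, truth = truth,
      frequencies = freq,
      effects = tibble(variant_id = paste0("sim", eff$causal),
                       effect = eff$beta[eff$causal]),
      config = cfg
    ),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort: %s>\n",
              paste(sprintf("%s=%d", names(table(x$subjects$cohort)),
                            as.integer(table(x$subjects$cohort))),
                    collapse = ", ")))
  invisible(x)
}

#' Realized risk and odds ratio of carrier status
#'
#' On an unascertained population sample, tabulates diagnosis against PDV
#' carrier status and reports the realized risk ratio
#' `P(case | carrier) / P(case | non-carrier)` and odds ratio.
#'
#' @param subjects Tibble with columns `status` (0/1) and `carrier_flag`
#'   (logical), from an unascertained sample.
#' @return One-row tibble: `risk_ratio`, `odds_ratio`, and the four cell
#'   counts of the 2x2 table.
#' @export
realized_risk_ratio <- function(subjects) {
  subjects <- as_tibble(subjects)
  stopifnot(all(c("status", "carrier_flag") %in% names(subjects)))
  a <- sum(subjects$carrier_flag & subjects$status == 1)   # carrier cases
  b <- sum(subjects$carrier_flag & subjects$status == 0)
  c_ <- sum(!subjects$carrier_flag & subjects$status == 1) # non-carrier cases
  d <- sum(!subjects$carrier_flag & subjects$status == 0)
  if ((a + b) == 0) abort("no carriers in sample; risk ratio undefined")
  if (c_ == 0) abort("no non-carrier cases in sample; risk ratio undefined")
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  or <- (a * d) / (b * c_)
  tibble(risk_ratio = rr, odds_ratio = or,
         carrier_cases = a, carrier_controls = b,
         noncarrier_cases = c_, noncarrier_controls = d)
}

#' Score-level liability population
#'
#' Draws liabilities (not genotypes) for a large population under the
#' threshold model: polygenic component `N(0, h2)`, carriers at `pdv_rate`
#' shifted by `delta`, environment `N(0, 1 - h2)`. Used for large-`n`
#' closure checks of the liability calculus where genotype-level simulation
#' adds nothing but runtime.
#'
#' @param n Number of subjects.
#' @param K Prevalence defining the threshold.
#' @param delta Carrier liability shift.
#' @param h2 Heritability of liability. Default 0.70.
#' @param pdv_rate Carrier probability.
#' @param seed Integer seed.
#' @return Tibble with `true_polygenic`, `true_liability`, `carrier_flag`,
#'   `status`.
#' @export
simulate_liability_population <- function(n, K, delta, h2 = 0.70,
                                          pdv_rate = 0.02, seed = 1L) {
  n <- check_count(n, "n")
  check_prob(K, "K")
  set.seed(seed)
  g <- rnorm(n, 0, sqrt(h2))
  carrier <- runif(n) < pdv_rate
  liab <- g + delta * carrier + rnorm(n, 0, sqrt(max(0, 1 - h2)))
  tibble(
    true_polygenic = g, true_liability = liab, carrier_flag = carrier,
    status = as.integer(liab > threshold_from_prevalence(K))
  )
}

#' Simulate trio polygenic scores for transmission tests
#'
#' Generates mother/father polygenic values `N(0, h2)`, child values as
#' midparent plus Mendelian segregation noise `N(0, h2/2)`, and child
#' diagnosis from the liability threshold. When `ascertained`, only trios
#' with an affected child are kept (the pTDT design). Observed scores are
#' the true polygenic values plus `N(0, noise_sd^2)` measurement noise,
#' emulating an imperfect PRS.
#'
#' @param n_trios Number of trios to return.
#' @param h2 Heritability of liability.
#' @param K Prevalence.
#' @param noise_sd Score measurement noise SD. Default `sqrt(h2)`, i.e. the
#'   score explains half the polygenic variance.
#' @param ascertained Keep only trios with affected children?
#' @param seed Integer seed.
#' @return Tibble with `trio_id`, `child`, `mother`, `father` observed
#'   scores.
#' @export
simulate_trio_scores <- function(n_trios, h2 = 0.70, K = 0.015,
                                 noise_sd = sqrt(h2), ascertained = TRUE,
                                 seed = 1L) {
  n_trios <- check_count(n_trios, "n_trios")
  set.seed(derive_seed(seed, "trios"))
  thr <- threshold_from_prevalence(K)
  out <- list()
  have <- 0
  drawn <- 0
  while (have < n_trios) {
    if (drawn > 1e7) abort("trio ascertainment infeasible at this prevalence")
    nb <- if (ascertained) ceiling((n_trios - have) / K * 1.2) else n_trios - have
    nb <- min(nb, 5e5)
    drawn <- drawn + nb
    gm <- rnorm(nb, 0, sqrt(h2))
    gf <- rnorm(nb, 0, sqrt(h2))
    gc <- (gm + gf) / 2 + rnorm(nb, 0, sqrt(h2 / 2))
    liab <- gc + rnorm(nb, 0, sqrt(max(0, 1 - h2)))
    keep <- if (ascertained) which(liab > thr) else seq_len(nb)
    keep <- keep[seq_len(min(length(keep), n_trios - have))]
    if (length(keep) > 0) {
      out[[length(out) + 1]] <- tibble(
        child = gc[keep] + rnorm(length(keep), 0, noise_sd),
        mother = gm[keep] + rnorm(length(keep), 0, noise_sd),
        father = gf[keep] + rnorm(length(keep), 0, noise_sd)
      )
      have <- have + length(keep)
    }
  }
  res <- bind_rows(out)
  res$trio_id <- sprintf("trio%05d", seq_len(nrow(res)))
  res[, c("trio_id", "child", "mother", "father")]
}
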