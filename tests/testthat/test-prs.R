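# Allele alignment, clumping, and scoring.

stats_row <- function(id, ea, oa, beta, p) {
  tibble::tibble(variant_id = id, effect_allele = ea, other_allele = oa,
                 effect = beta, p = p)
}

test_that("allele alignment keeps, flips, and drops as documented", {
  g <- toy_genotypes(matrix(rbinom(40, 2, 0.5), 10, 4),
                     a1 = c("A", "C", "A", "G"), a2 = c("G", "T", "T", "C"))
  st <- dplyr::bind_rows(
    stats_row("v001", "A", "G", 0.5, 0.001),   # matches counted allele
    stats_row("v002", "T", "C", 0.3, 0.01),    # swapped -> negate
    stats_row("v003", "A", "T", 0.2, 0.02),    # ambiguous A/T -> dropped
    stats_row("v004", "G", "C", 0.1, 0.03),    # ambiguous C/G -> dropped
    stats_row("v999", "A", "G", 0.9, 0.04)     # unknown id -> dropped
  )
  suppressMessages(al <- align_alleles(st, g))
  expect_setequal(al$variant_id, c("v001", "v002"))
  expect_equal(al$effect[al$variant_id == "v001"], 0.5)
  expect_equal(al$effect[al$variant_id == "v002"], -0.3)
  expect_equal(unname(attr(al, "dropped")),
               c(1L, 2L, 0L))
  suppressMessages(
    al2 <- align_alleles(st, g, drop_ambiguous = FALSE))
  expect_true("v003" %in% al2$variant_id)
  expect_error(suppressMessages(align_alleles(stats_row("zz", "A", "G", 1, 0.5), g)),
               "zero variants")
})

test_that("clumping keeps the best of a perfect-LD block and free variants", {
  set.seed(50)
  v1 <- rbinom(200, 2, 0.5)
  x <- cbind(v1, v1, v1, rbinom(200, 2, 0.4), rbinom(200, 2, 0.6))
  g <- toy_genotypes(x, pos = c(100, 200, 300, 5e5, 9e5))
  st <- dplyr::bind_rows(
    stats_row("v001", "A", "G", 0.1, 1e-5),
    stats_row("v002", "A", "G", 0.1, 1e-4),
    stats_row("v003", "A", "G", 0.1, 1e-3),
    stats_row("v004", "A", "G", 0.1, 5e-3),
    stats_row("v005", "A", "G", 0.1, 0.5)      # above threshold
  )
  idx <- clump(st, g, clump_r2 = 0.1, clump_window_kb = 250,
               p_threshold = 0.01)
  expect_setequal(idx, c("v001", "v004"))
  # independent variants below threshold all survive
  idx2 <- clump(st[4:5, ], g, p_threshold = 0.6)
  expect_setequal(idx2, c("v004", "v005"))
})

test_that("clumping trace equals a brute-force greedy oracle on a hand-built block", {
  set.seed(51)
  n <- 400
  a <- rbinom(n, 2, 0.5)
  b <- ifelse(runif(n) < 0.8, a, rbinom(n, 2, 0.5))  # high LD with a
  c_ <- rbinom(n, 2, 0.3)
  d <- ifelse(runif(n) < 0.8, c_, rbinom(n, 2, 0.3)) # high LD with c
  e <- rbinom(n, 2, 0.6)
  x <- cbind(a, b, c_, d, e)
  g <- toy_genotypes(x, pos = c(1000, 2000, 3000, 4000, 300000))
  ps <- c(1e-6, 1e-5, 1e-4, 2e-4, 1e-3)
  st <- dplyr::bind_rows(lapply(1:5, function(i) {
    stats_row(sprintf("v%03d", i), "A", "G", 0.1, ps[i])
  }))
  r2_thr <- 0.1; win <- 50
  # brute-force greedy oracle recomputed from scratch
  alive <- 1:5
  kept <- integer(0)
  pos <- c(1000, 2000, 3000, 4000, 300000)
  while (length(alive) > 0) {
    i <- alive[which.min(ps[alive])]
    kept <- c(kept, i)
    alive <- setdiff(alive, i)
    for (j in alive) {
      if (abs(pos[j] - pos[i]) <= win * 1000 &&
          suppressWarnings(cor(x[, i], x[, j]))^2 > r2_thr) {
        alive <- setdiff(alive, j)
      }
    }
  }
  idx <- clump(st, g, clump_r2 = r2_thr, clump_window_kb = win,
               p_threshold = 1)
  expect_identical(idx, sprintf("v%03d", kept))
  # clumped set is a subset of the thresholded set with no offending pair
  expect_true(all(ps[match(idx, sprintf("v%03d", 1:5))] < 1))
  for (i in seq_along(idx)) {
    for (j in seq_len(i - 1)) {
      ii <- match(idx[i], sprintf("v%03d", 1:5))
      jj <- match(idx[j], sprintf("v%03d", 1:5))
      if (abs(pos[ii] - pos[jj]) <= win * 1000) {
        expect_lt(suppressWarnings(cor(x[, ii], x[, jj]))^2, r2_thr)
      }
    }
  }
})

test_that("scoring is linear in effects and respects allele orientation", {
  g <- toy_genotypes(matrix(c(0L, 1L, 2L), 3, 1), ids = c("a", "b", "c"))
  st <- stats_row("v001", "A", "G", 0.5, 0.001)
  sc <- prs_score(g, st, "v001")
  expect_equal(sc$raw, c(0, 0.5, 1.0))
  # doubling effects doubles raw scores
  st2 <- st; st2$effect <- 1.0
  expect_equal(prs_score(g, st2, "v001")$raw, 2 * sc$raw)
  # allele swap plus effect negation leaves the standardized score intact
  gsw <- toy_genotypes(matrix(c(2L, 1L, 0L), 3, 1), ids = c("a", "b", "c"))
  stn <- st; stn$effect <- -0.5
  expect_equal(prs_score(gsw, stn, "v001")$score, sc$score, tolerance = 1e-12)
  # zero effects give flat raw scores
  st0 <- st; st0$effect <- 0
  expect_true(all(prs_score(g, st0, "v001")$raw == 0))
})

test_that("a PRS trained on one simulated cohort transfers to another", {
  cfg <- sim_config(n_cases = 150, n_matched_controls = 150,
                    n_pool_controls = 100, k_clusters = 1, m_snps = 600,
                    m_causal = 150, prevalence = 0.05, pdv_rate = 0, seed = 60)
  train <- simulate_cohort(cfg)
  st <- simulate_summary_stats(train$genotypes, train$subjects$status)
  cfg2 <- cfg; cfg2$seed <- 61L
  target <- simulate_cohort(cfg2)
  suppressMessages(al <- align_alleles(st, target$genotypes))
  pool_ids <- target$subjects$subject_id[target$subjects$cohort == "pool_control"]
  idx <- clump(al, geno_subset(target, pool_ids), p_threshold = 0.05)
  an_ids <- target$subjects$subject_id[target$subjects$cohort != "pool_control"]
  sc <- prs_score(geno_subset(target, an_ids), al, idx, name = "PRS")
  truth <- target$truth$true_polygenic[match(sc$subject_id,
                                             target$truth$subject_id)]
  expect_gt(cor(sc$score, truth), 0.05)
})
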