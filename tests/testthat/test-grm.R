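# Frequency shrinkage and the three GRM standardizations.

make_pool <- function(n_per_cluster, freqs_by_cluster, seed = 1) {
  # freqs_by_cluster: list of per-variant frequency vectors
  set.seed(seed)
  k <- length(freqs_by_cluster)
  m <- length(freqs_by_cluster[[1]])
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rbinom(n_per_cluster[i] * m, 2,
                  rep(freqs_by_cluster[[i]], each = n_per_cluster[i])),
           n_per_cluster[i], m)
  }))
  list(genotypes = toy_genotypes(x),
       clusters = factor(rep(paste0("C", seq_len(k)), n_per_cluster)))
}

test_that("EB shrinkage is the stated beta-binomial posterior mean", {
  # engineer raw cluster frequency 0.30 (n_k = 50), pooled 0.50, prior 100:
  # posterior mean must be (30 + 100*0.5) / (100 + 100) = 0.40
  # cluster 1: allele count 30 of 100 -> 5 subjects with 2, 20 with 1
  c1 <- c(rep(2L, 5), rep(1L, 20), rep(0L, 25))
  # cluster 2: allele count 70 of 100 so the pool sits at 0.50
  c2 <- c(rep(2L, 25), rep(1L, 20), rep(0L, 5))
  g <- toy_genotypes(matrix(c(c1, c2), ncol = 1))
  cl <- factor(rep(c("C1", "C2"), each = 50))
  fr <- estimate_frequencies(g, cl, prior_m = 100)
  expect_equal(unname(fr$raw[1, "C1"]), 0.30)
  expect_equal(unname(fr$pooled[1]), 0.50)
  expect_equal(unname(fr$eb[1, "C1"]), 0.40)
  # independent beta-binomial oracle: posterior mean of Beta(m*pbar, m*(1-pbar))
  # prior updated with 30 successes in 100 trials
  m <- 100; pbar <- 0.5
  post <- (m * pbar + 30) / (m + 100)
  expect_equal(unname(fr$eb[1, "C1"]), post)
  # EB lies between raw and pooled
  expect_true(fr$eb[1, "C1"] > fr$raw[1, "C1"] &&
                fr$eb[1, "C1"] < fr$pooled[1])
})

test_that("single cluster and large-n limits collapse shrinkage", {
  pool <- make_pool(80, list(runif(30, 0.2, 0.8)), seed = 3)
  fr <- estimate_frequencies(pool$genotypes, pool$clusters)
  expect_equal(unname(fr$eb[, 1]), unname(fr$pooled), tolerance = 1e-12)
  expect_equal(unname(fr$raw[, 1]), unname(colMeans(unclass(pool$genotypes)) / 2))
  # growing n_k with fixed prior strength pulls EB onto the raw frequency
  p <- c(0.3, 0.6)
  big <- make_pool(c(5000, 5000), list(p, rev(p)), seed = 4)
  fr_big <- estimate_frequencies(big$genotypes, big$clusters, prior_m = 50)
  expect_equal(unname(fr_big$eb[, "C1"]), unname(fr_big$raw[, "C1"]),
               tolerance = 0.01)
})

test_that("moment estimate of divergence tracks the simulated Fst", {
  f <- draw_structured_frequencies(2000, 2, fst = 0.05, seed = 10)
  set.seed(11)
  n <- 400
  x <- rbind(
    matrix(rbinom(n * 2000, 2, rep(f$cluster[, 1], each = n)), n, 2000),
    matrix(rbinom(n * 2000, 2, rep(f$cluster[, 2], each = n)), n, 2000))
  pool <- toy_genotypes(x)
  fr <- estimate_frequencies(pool, factor(rep(c("C1", "C2"), each = n)))
  # divergence measured against the pooled mean is about Fst/2 for two
  # equal-weight clusters (each cluster sits Fst/2 from the midpoint)
  expect_equal(fr$fhat, 0.025, tolerance = 0.3)
  expect_equal(fr$prior_m, (1 - fr$fhat) / fr$fhat)
})

test_that("standardization has the stated closed form and centers clusters", {
  # pool engineered to an exact pooled frequency of 0.5 per variant
  col <- c(rep(0L, 50), rep(1L, 100), rep(2L, 50))
  pool_g <- toy_genotypes(cbind(col, col, col))
  fr <- estimate_frequencies(pool_g, factor(rep("C1", 200)))
  x <- matrix(c(2L, 1L, 0L), 1)
  g <- toy_genotypes(x, ids = "s1")
  z <- standardize_genotypes(g, fr, "POP")
  # x = 2, p = 0.5 -> (2 - 1)/sqrt(0.5); x = 2p -> 0
  expect_equal(z[1, 1], 1.41421, tolerance = 1e-4)
  expect_equal(z[1, 2], 0)
  expect_equal(z[1, 3], -1.41421, tolerance = 1e-4)
  # missing dosages standardize to exactly 0
  gm <- toy_genotypes(matrix(c(NA_integer_, 1L, 2L), 1))
  expect_equal(standardize_genotypes(gm, fr, "POP")[1, 1], 0)
  # CLS standardization centers each cluster of the pool itself
  pool2 <- make_pool(c(150, 150), list(runif(40, 0.2, 0.8),
                                       runif(40, 0.2, 0.8)), seed = 6)
  fr2 <- estimate_frequencies(pool2$genotypes, pool2$clusters)
  z2 <- standardize_genotypes(pool2$genotypes, fr2, "CLS",
                              clusters = pool2$clusters)
  cm <- tapply(seq_len(nrow(z2)), pool2$clusters,
               function(i) mean(colMeans(z2[i, , drop = FALSE])))
  expect_true(all(abs(cm) < 0.05))
})

test_that("GRM has unit-scale diagonal and near-zero off-diagonals under HWE", {
  set.seed(8)
  p <- runif(10000, 0.1, 0.9)
  n <- 200
  x <- matrix(rbinom(n * 10000, 2, rep(p, each = n)), n, 10000)
  g <- toy_genotypes(x)
  grm <- compute_grm(g, "STD")
  offd <- grm$matrix[upper.tri(grm$matrix)]
  expect_lt(abs(mean(offd)), 0.01)
  expect_equal(mean(diag(grm$matrix)), 1, tolerance = 0.02)
  # a duplicated subject relates to itself about as strongly as its diagonal
  x2 <- rbind(x[1:60, ], x[1, ])
  g2 <- toy_genotypes(x2)
  grm2 <- compute_grm(g2, "STD")
  expect_equal(grm2$matrix[1, 61], grm2$matrix[1, 1], tolerance = 0.05)
  # the cross-product modes are positive semidefinite when M >= N
  pool <- make_pool(100, list(runif(300, 0.2, 0.8)), seed = 9)
  fr <- estimate_frequencies(pool$genotypes, pool$clusters)
  an <- toy_genotypes(matrix(rbinom(40 * 300, 2, 0.5), 40, 300))
  gp <- compute_grm(an, "POP", fr)
  ev <- eigen(gp$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("GRM is invariant to variant and subject ordering", {
  set.seed(13)
  x <- matrix(rbinom(30 * 200, 2, 0.4), 30, 200)
  g <- toy_genotypes(x)
  a <- compute_grm(g, "STD")$matrix
  pv <- sample(200)
  gv <- toy_genotypes(x[, pv], pos = seq_len(200))
  expect_equal(unname(compute_grm(gv, "STD")$matrix), unname(a),
               tolerance = 1e-10)
  ps <- sample(30)
  gs <- toy_genotypes(x[ps, ], ids = sprintf("s%02d", ps))
  b <- compute_grm(gs, "STD")$matrix
  expect_equal(unname(b[order(ps), order(ps)]), unname(a), tolerance = 1e-10)
})

test_that("POP standardization inflates within-cluster relatedness that CLS removes", {
  f <- draw_structured_frequencies(4000, 2, fst = 0.05, seed = 14)
  build <- function(n, seed) {
    set.seed(seed)
    x <- rbind(
      matrix(rbinom(n * 4000, 2, rep(f$cluster[, 1], each = n)), n, 4000),
      matrix(rbinom(n * 4000, 2, rep(f$cluster[, 2], each = n)), n, 4000))
    list(g = toy_genotypes(x), cl = factor(rep(c("C1", "C2"), each = n)))
  }
  pool <- build(250, 15)
  fr <- estimate_frequencies(pool$g, pool$cl)
  an <- build(40, 16)
  gpop <- compute_grm(an$g, "POP", fr)
  gcls <- compute_grm(an$g, "CLS", fr, clusters = an$cl)
  within <- function(gm, lev) {
    i <- which(an$cl == lev)
    m <- gm$matrix[i, i]
    mean(m[upper.tri(m)])
  }
  expect_gt(within(gpop, "C1"), within(gcls, "C1") + 0.01)
  expect_lt(abs(within(gcls, "C1")), 0.01)
  # single cluster: CLS and POP coincide once the prior matches the pool
  pool1 <- make_pool(200, list(runif(100, 0.2, 0.8)), seed = 17)
  fr1 <- estimate_frequencies(pool1$genotypes, pool1$clusters)
  an1 <- toy_genotypes(matrix(rbinom(20 * 100, 2, 0.5), 20, 100))
  g_cls <- compute_grm(an1, "CLS", fr1,
                       clusters = factor(rep("C1", 20)))
  g_pop <- compute_grm(an1, "POP", fr1)
  expect_equal(g_cls$matrix, g_pop$matrix, tolerance = 1e-10)
})

test_that("degenerate GRM inputs error out", {
  expect_error(compute_grm(toy_genotypes(matrix(1L, 1, 3)), "STD"),
               "2 subjects")
  expect_error(compute_grm(toy_genotypes(matrix(1L, 5, 3)), "STD"),
               "usable")
  pool <- make_pool(50, list(rep(0.5, 2)), seed = 18)
  fr <- estimate_frequencies(pool$genotypes, pool$clusters)
  expect_error(compute_grm(toy_genotypes(matrix(0:1, 4, 2)), "CLS"),
               "frequencies")
})
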