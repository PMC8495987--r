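# Pruning, eigenvectors, clustering, and optimal matching.

test_that("pruning removes the later member of perfectly correlated pairs", {
  set.seed(1)
  base <- matrix(rbinom(60 * 4, 2, 0.4), 60, 4)
  x <- cbind(base[, 1], base[, 1], base[, 2:4])   # v001 duplicated as v002
  g <- toy_genotypes(x)
  kept <- ld_prune(g, window = 5, step = 1, r2_max = 0.64)
  expect_true("v001" %in% kept)
  expect_false("v002" %in% kept)
  # vacuous threshold keeps everything (r-squared never strictly exceeds 1)
  expect_length(ld_prune(g, window = 5, step = 1, r2_max = 1.0), 5)
})

test_that("independent variants survive pruning and coding swap leaves it invariant", {
  set.seed(7)
  x <- matrix(rbinom(2000 * 40, 2, runif(40, 0.2, 0.8)), 2000, 40,
              byrow = TRUE)
  g <- toy_genotypes(x)
  kept <- ld_prune(g)
  expect_length(kept, 40)
  # dosage recoding x -> 2 - x preserves r-squared, hence the pruned set
  g2 <- toy_genotypes(2L - x)
  expect_identical(ld_prune(g2), kept)
})

test_that("monomorphic variants are retained despite undefined correlation", {
  set.seed(2)
  x <- cbind(rbinom(50, 2, 0.5), rep(1L, 50), rbinom(50, 2, 0.5))
  kept <- ld_prune(toy_genotypes(x), window = 3, step = 1)
  expect_true("v002" %in% kept)
})

test_that("eigenvectors separate simulated clusters and obey conventions", {
  cfg <- sim_config(n_cases = 10, n_pool_controls = 10, k_clusters = 2,
                    fst = 0.2, m_snps = 500, seed = 5)
  pop <- simulate_population(cfg, 300)
  sp <- compute_eigenvectors(pop$genotypes, d = 2)
  expect_equal(unname(colSums(sp$vectors^2)), c(1, 1), tolerance = 1e-8)
  # sign convention: dominant coordinate positive
  for (j in 1:2) {
    expect_gt(sp$vectors[which.max(abs(sp$vectors[, j])), j], 0)
  }
  km <- kmeans(sp$vectors[, 1], 2, nstart = 10)$cluster
  expect_gt(adjusted_rand(km, pop$subjects$cluster), 0.9)
  # subject-order invariance up to the sign convention
  perm <- sample(nrow(pop$genotypes))
  gperm <- polyrisk:::new_genotype_matrix(
    unclass(pop$genotypes)[perm, , drop = FALSE],
    rownames(pop$genotypes)[perm], variants(pop$genotypes))
  sp2 <- compute_eigenvectors(gperm, d = 2)
  expect_equal(abs(sp2$vectors[match(sp$ids, sp2$ids), 1]),
               abs(sp$vectors[, 1]), tolerance = 1e-6)
  expect_error(compute_eigenvectors(pop$genotypes, d = 10000), "rank")
  # identical genotypes for everyone: no polymorphic variant survives
  flat <- toy_genotypes(matrix(1L, 20, 10))
  expect_error(compute_eigenvectors(flat, d = 1), "usable|rank")
})

test_that("k-means clustering recovers well-separated clusters deterministically", {
  cfg <- sim_config(n_cases = 10, n_pool_controls = 10, k_clusters = 4,
                    fst = 0.15, m_snps = 800, seed = 6)
  pop <- simulate_population(cfg, 400)
  sp <- compute_eigenvectors(pop$genotypes, d = 3)
  cl <- cluster_subjects(sp, k = 4, seed = 3)
  expect_gt(adjusted_rand(cl$clusters, pop$subjects$cluster), 0.95)
  cl2 <- cluster_subjects(sp, k = 4, seed = 3)
  expect_identical(cl$clusters, cl2$clusters)
  # k = 1 trivially assigns everyone together
  one <- cluster_subjects(sp, k = 1)
  expect_equal(length(unique(one$clusters)), 1L)
  expect_error(cluster_subjects(sp, k = 10000), "exceed")
  # silhouette-based selection lands on the simulated k for clean structure
  auto <- cluster_subjects(sp, seed = 3)
  expect_equal(auto$n_clusters, 4L)
})

test_that("assignment solver equals brute-force enumeration on small instances", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(2:6, 1)
    m <- n + sample(0:2, 1)
    cost <- matrix(runif(n * m), n, m)
    asg <- polyrisk:::solve_assignment(cost)
    got <- sum(cost[cbind(seq_len(n), asg)])
    best <- min(vapply(perms(seq_len(m)), function(p) {
      sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    }, numeric(1)))
    expect_equal(got, best, tolerance = 1e-10)
    expect_false(anyDuplicated(asg) > 0)
  }
  # 2x2 sanity case: diagonal pairing wins
  asg <- polyrisk:::solve_assignment(matrix(c(1, 10, 10, 1), 2, 2))
  expect_equal(asg, c(1L, 2L))
})

test_that("matching is within-cluster, optimal, and beats random pairing", {
  cfg <- sim_config(n_cases = 50, n_matched_controls = 60,
                    n_pool_controls = 10, k_clusters = 2, fst = 0.1,
                    m_snps = 400, prevalence = 0.1, seed = 12)
  co <- simulate_cohort(cfg)
  sp <- cluster_subjects(compute_eigenvectors(co$genotypes, d = 2), k = 2)
  subj <- co$subjects[co$subjects$cohort != "pool_control",
                      c("subject_id", "status")]
  pr <- match_pairs(sp, subj)
  expect_equal(nrow(pr), 50)
  expect_length(attr(pr, "unmatched_controls"), 10)
  # paired subjects share a cluster
  cl_of <- function(id) sp$clusters[match(id, sp$ids)]
  expect_true(all(cl_of(pr$case_id) == cl_of(pr$control_id)))
  # each id appears at most once
  expect_false(anyDuplicated(c(pr$case_id, pr$control_id)) > 0)
  # mean matched distance below mean random case-control distance
  pos <- sp$vectors
  rand <- mean(vapply(1:200, function(b) {
    i <- sample(which(subj$status == 1), 1)
    j <- sample(which(subj$status == 0), 1)
    sqrt(sum((pos[match(subj$subject_id[i], sp$ids), ] -
                pos[match(subj$subject_id[j], sp$ids), ])^2))
  }, numeric(1)))
  expect_lt(attr(pr, "mean_distance"), rand)
})

test_that("degenerate matching cases behave as documented", {
  vec <- matrix(c(0, 0, 1, 5), ncol = 1,
                dimnames = list(c("case1", "ctrl1", "case2", "ctrl2"), "EV1"))
  sp <- structure(list(vectors = vec, values = 1,
                       ids = rownames(vec),
                       clusters = factor(c("C1", "C1", "C2", "C2")),
                       n_clusters = 2),
                  class = "ancestry_space")
  subj <- tibble::tibble(subject_id = rownames(vec), status = c(1, 0, 1, 0))
  pr <- match_pairs(sp, subj)
  expect_equal(pr$distance[pr$case_id == "case1"], 0)
  # a cluster with cases but no controls warns and leaves them unmatched
  sp$clusters <- factor(c("C1", "C1", "C2", "C1"))
  subj2 <- tibble::tibble(subject_id = rownames(vec), status = c(1, 0, 1, 1))
  expect_warning(pr2 <- match_pairs(sp, subj2), "no controls")
  expect_true("case2" %in% attr(pr2, "unmatched_cases"))
})
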