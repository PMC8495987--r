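# Logistic evaluation, WGRS combination, pTDT, and burden contrasts.

test_that("logistic evaluation matches an independent Newton solver on 8 observations", {
  s <- c(-1.5, -1.0, -0.5, -0.2, 0.2, 0.6, 1.1, 1.6)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  ev <- evaluate_score(s, y)
  # hand-rolled Newton-Raphson for the two-parameter logistic likelihood
  b <- c(0, 0)
  X <- cbind(1, s)
  for (it in 1:50) {
    mu <- 1 / (1 + exp(-drop(X %*% b)))
    grad <- crossprod(X, y - mu)
    hess <- crossprod(X * (mu * (1 - mu)), X)
    b <- b + solve(hess, grad)
  }
  expect_equal(ev$beta, b[2], tolerance = 1e-6)
  expect_equal(ev$or, exp(b[2]), tolerance = 1e-6)
  # Nagelkerke from explicitly evaluated likelihoods
  mu1 <- 1 / (1 + exp(-drop(X %*% b)))
  l1 <- prod(mu1^y * (1 - mu1)^(1 - y))
  p0 <- mean(y)
  l0 <- prod(p0^y * (1 - p0)^(1 - y))
  nag <- (1 - (l0 / l1)^(2 / 8)) / (1 - l0^(2 / 8))
  expect_equal(ev$pseudo_r2, nag, tolerance = 1e-6)
})

test_that("null scores evaluate to OR 1 and near-zero pseudo-R2", {
  set.seed(70)
  s <- rnorm(4000)
  y <- rbinom(4000, 1, 0.5)
  ev <- evaluate_score(s, y)
  expect_equal(ev$or, 1, tolerance = 0.1)
  expect_lt(ev$pseudo_r2, 0.01)
  expect_true(ev$ci[1] < ev$or && ev$or < ev$ci[2])
  expect_error(evaluate_score(s, rep(1, 4000)), "both statuses")
})

test_that("complete separation is flagged with an infinite-OR sentinel", {
  s <- c(-(5:1), 1:5)
  y <- as.integer(s > 0)
  ev <- evaluate_score(s, y)
  expect_true(ev$separation)
  expect_true(is.infinite(ev$or))
  expect_true(glance(ev)$separation)
})

test_that("WGRS weights reproduce the pseudo-R2 arithmetic", {
  w <- wgrs_weights(c(GP = 7.80, ASD = 1.23, SCZ = 0.95))
  expect_equal(w$weight, c(0.7816, 0.1232, 0.0952), tolerance = 1e-4)
  expect_equal(sum(w$weight), 1)
  expect_equal(wgrs_weights(c(a = 1, b = 3), scheme = "equal")$weight,
               c(0.5, 0.5))
  expect_warning(w0 <- wgrs_weights(c(a = 0, b = 0)), "equal")
  expect_equal(w0$weight, c(0.5, 0.5))
})

test_that("WGRS of identical components equals each component", {
  set.seed(71)
  s <- standardize_vec <- scale(rnorm(300))[, 1]
  y <- rbinom(300, 1, plogis(s))
  comp <- new_sv <- tibble::tibble(subject_id = sprintf("s%03d", 1:300),
                                   score = s)
  res <- combine_wgrs(list(a = comp, b = comp, c = comp), y)
  expect_equal(res$score$score, s, tolerance = 1e-8)
  expect_equal(res$weights$weight, rep(1 / 3, 3), tolerance = 1e-10)
  # equal scheme with two components is proportional to their mean
  comp2 <- comp; comp2$score <- scale(rnorm(300))[, 1]
  res2 <- combine_wgrs(list(a = comp, b = comp2), y, scheme = "equal")
  mean_sc <- (comp$score + comp2$score) / 2
  expect_equal(res2$score$score, (mean_sc - mean(mean_sc)) / sd(mean_sc),
               tolerance = 1e-10)
})

test_that("WGRS discriminates at least as well as its best component in-sample", {
  set.seed(72)
  reps <- replicate(6, {
    n <- 1500
    liab <- rnorm(n)
    comp <- lapply(c(0.6, 0.25, 0.15), function(r2) {
      sc <- sqrt(r2) * liab + rnorm(n, 0, sqrt(1 - r2))
      tibble::tibble(subject_id = sprintf("s%04d", 1:n),
                     score = (sc - mean(sc)) / sd(sc))
    })
    names(comp) <- c("GP", "ASD", "SCZ")
    y <- as.integer(liab + rnorm(n, 0, 0.8) > 1)
    res <- combine_wgrs(comp, y)
    best <- max(vapply(comp, function(cc) evaluate_score(cc$score, y)$pseudo_r2,
                       numeric(1)))
    evaluate_score(res$score$score, y)$pseudo_r2 - best
  })
  expect_true(all(reps > -1e-6))
})

test_that("pTDT closed forms and invariances hold", {
  # children identical to midparent: zero deviation, t = 0
  tr <- tibble::tibble(child = c(1, 2, 3, 4), mother = c(0, 2, 2, 4),
                       father = c(2, 2, 4, 4))
  res <- ptdt(tr)
  expect_equal(res$mean_deviation, 0)
  expect_equal(res$t, 0)
  # constant offset c with midparent SD s gives deviation c/s
  tr2 <- tr; tr2$child <- tr2$child + 0.7
  s <- sd((tr$mother + tr$father) / 2)
  expect_equal(ptdt(tr2)$mean_deviation, 0.7 / s, tolerance = 1e-12)
  # adding any constant to every member changes nothing
  tr3 <- tr2 + 100
  expect_equal(ptdt(tr3)$mean_deviation, ptdt(tr2)$mean_deviation)
  expect_error(ptdt(tibble::tibble(child = 1:3, mother = rep(1, 3),
                                   father = rep(1, 3))), "zero variance")
})

test_that("pTDT detects over-transmission in ascertained trios", {
  hits <- vapply(1:10, function(i) {
    tr <- simulate_trio_scores(500, h2 = 0.7, K = 0.015, seed = 100 + i)
    res <- ptdt(tr)
    res$mean_deviation > 0 && res$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("burden contrasts order groups and flag the null correctly", {
  set.seed(73)
  n <- 600
  ids <- sprintf("s%04d", 1:n)
  status <- rep(c(1, 0), each = n / 2)
  carrier <- status == 1 & runif(n) < 0.3
  sc <- rnorm(n, 0.4 * status - 0.25 * carrier)
  score <- tibble::tibble(subject_id = ids, score = (sc - mean(sc)) / sd(sc))
  calls <- tibble::tibble(
    subject_id = ids,
    status = ifelse(carrier, "carrier", "non-carrier"),
    most_severe = ifelse(carrier,
                         sample(c("CNV", "PTV", "MIS"), n, replace = TRUE),
                         NA_character_),
    assayed = TRUE)
  subj <- tibble::tibble(subject_id = ids, status = status)
  suppressWarnings(bc <- burden_contrasts(score, subj, calls, n_boot = 200))
  g <- bc$groups
  m <- function(nm) g$mean[g$group == nm]
  expect_true(m("controls") < m("carrier_cases"))
  expect_true(m("carrier_cases") < m("noncarrier_cases"))
  expect_lt(bc$carrier_or$or, 1)
  # permuted carrier labels give a null OR
  calls2 <- calls
  calls2$status <- sample(calls$status)
  suppressWarnings(bc2 <- burden_contrasts(score, subj, calls2, n_boot = 50))
  expect_equal(bc2$carrier_or$or, 1, tolerance = 0.25)
  # all-equal scores give all-equal group means
  score0 <- score; score0$score <- 0
  suppressWarnings(bc0 <- burden_contrasts(score0, subj, calls, n_boot = 50))
  expect_true(all(abs(bc0$groups$mean) < 1e-12))
})
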