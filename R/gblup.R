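#' G-BLUP prediction of genetic values for held-out subjects
#'
#' Solves the ridge form of the G-BLUP mixed-model equations: with
#' `A = K_train + lambda I` and `lambda = (1 - h2) / h2`, predictions for
#' the test subjects are `K_test,train A^{-1} (y - mean(y))`. The phenotype
#' is the 0/1 case indicator centered on the training set; predictions are
#' returned unstandardized.
#'
#' @param grm A `grm` covering both training and test subjects.
#' @param train_ids,test_ids Disjoint subject id vectors present in the GRM.
#' @param train_phenotypes Numeric phenotype for `train_ids` (same order).
#' @param h2 Heritability of liability used to set the ridge; default 0.70.
#' @return Tibble `subject_id`, `prediction` for the test subjects.
#' @export
blup_predict <- function(grm, train_ids, train_phenotypes, test_ids,
                         h2 = 0.70) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(h2) || length(h2) != 1 || h2 <= 0 || h2 >= 1) {
    abort("`h2` must lie strictly in (0, 1)")
  }
  if (length(intersect(train_ids, test_ids)) > 0) {
    abort("train and test ids must be disjoint")
  }
  miss <- setdiff(c(train_ids, test_ids), grm$ids)
  if (length(miss) > 0) abort("ids absent from GRM")
  stopifnot(length(train_phenotypes) == length(train_ids))
  lambda <- (1 - h2) / h2
  ktr <- grm$matrix[train_ids, train_ids, drop = FALSE]
  kte <- grm$matrix[test_ids, train_ids, drop = FALSE]
  yc <- train_phenotypes - mean(train_phenotypes)
  a <- ktr + diag(lambda, length(train_ids))
  sol <- tryCatch(solve(a, yc), error = function(e) {
    abort(paste("singular G-BLUP system; consider jittering the GRM diagonal:",
                conditionMessage(e)))
  })
  tibble(subject_id = test_ids, prediction = unname(drop(kte %*% sol)))
}

# Precompute the leave-pair-out machinery for one GRM + pair set.
# Exploits the identity g_S = y*_S - W^{-1} (A^{-1} y*)_S for held-out set
# S, with W = (A^{-1})_{S,S} and y* the phenotype centered on the fold's
# training subjects -- the collapsed form of the block (Schur) downdate of
# A^{-1}, exact for every fold.
lpo_engine <- function(grm, pairs, h2 = 0.70) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(h2) || h2 <= 0 || h2 >= 1) abort("`h2` must lie in (0, 1)")
  if (nrow(pairs) < 2) abort("need at least 2 matched pairs")
  ids <- c(rbind(pairs$case_id, pairs$control_id))
  if (anyDuplicated(ids)) abort("each subject may appear in only one pair")
  miss <- setdiff(ids, grm$ids)
  if (length(miss) > 0) abort("pair members absent from GRM")
  n <- length(ids)
  lambda <- (1 - h2) / h2
  a <- grm$matrix[ids, ids] + diag(lambda, n)
  ainv <- tryCatch({
    ch <- chol(a)
    chol2inv(ch)
  }, error = function(e) {
    inform("GRM factorization failed; retrying with 1e-8 diagonal jitter")
    chol2inv(chol(a + diag(1e-8, n)))
  })
  pair_rows <- matrix(seq_len(n), nrow = 2)   # column p = rows of pair p
  u1 <- ainv %*% rep(1, n)
  # 2x2 inverse blocks of ainv per pair
  winv <- lapply(seq_len(ncol(pair_rows)), function(p) {
    s <- pair_rows[, p]
    solve(ainv[s, s])
  })
  predict_fun <- function(y) {
    # y: n-vector or n x B matrix in `ids` order; returns same shape of
    # leave-pair-out predictions
    y <- as.matrix(y)
    stopifnot(nrow(y) == n)
    v <- ainv %*% y
    tot <- colSums(y)
    out <- matrix(0, n, ncol(y))
    for (p in seq_len(ncol(pair_rows))) {
      s <- pair_rows[, p]
      mS <- (tot - colSums(y[s, , drop = FALSE])) / (n - 2)
      ystar <- y[s, , drop = FALSE] - rep(mS, each = 2)
      vstar <- v[s, , drop = FALSE] - u1[s] %*% t(mS)
      out[s, ] <- ystar - winv[[p]] %*% vstar
    }
    out
  }
  list(ids = ids, n = n, predict = predict_fun)
}

#' Leave-matched-pair-out G-BLUP genomic prediction
#'
#' The training plan holds out one matched case-control pair at a time and
#' predicts its two members from the remaining N - 2 subjects, iterating
#' over all pairs; concatenated predictions are standardized to mean 0 and
#' SD 1. Rather than refitting N/2 systems, a single inverse of
#' `A = K + lambda I` is downdated per fold via the block/Schur identity,
#' which is algebraically exact (and verified against the naive refit in
#' the test suite).
#'
#' @param grm A `grm` covering all paired subjects.
#' @param pairs A `matched_pairs` (or tibble with `case_id`, `control_id`).
#' @param subjects Tibble with `subject_id` and `status` (1 case,
#'   0 control), or a named numeric phenotype vector.
#' @param h2 Liability heritability fixing the ridge; default 0.70.
#' @return A `score_vector` tibble: `subject_id`, `score` (standardized GP)
#'   and `raw` (unstandardized prediction); attribute `name = "GP"`.
#' @export
leave_pair_out_gp <- function(grm, pairs, subjects, h2 = 0.70) {
  eng <- lpo_engine(grm, pairs, h2)
  y <- phenotype_for(subjects, eng$ids)
  raw <- drop(eng$predict(y))
  new_score(tibble(subject_id = eng$ids, score = standardize(raw), raw = raw),
            name = "GP",
            provenance = sprintf("leave-pair-out G-BLUP, h2 = %g, %s GRM, %d variants",
                                 h2, grm$mode, grm$m_variants))
}

phenotype_for <- function(subjects, ids) {
  if (is.numeric(subjects) && !is.null(names(subjects))) {
    y <- subjects[ids]
  } else {
    subjects <- as_tibble(subjects)
    stopifnot(all(c("subject_id", "status") %in% names(subjects)))
    y <- subjects$status[match(ids, subjects$subject_id)]
  }
  if (anyNA(y)) abort("phenotype missing for some paired subjects")
  as.numeric(y)
}

new_score <- function(df, name, provenance = "", standardized = TRUE) {
  structure(df, name = name, provenance = provenance,
            standardized = standardized,
            class = c("score_vector", class(df)))
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector %s: %d subjects%s>\n", attr(x, "name"), nrow(x),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  NextMethod()
}

#' Genomic-control inflation factor
#'
#' `lambda = median(statistics) / qchisq(0.5, 1)`, the ratio of the median
#' observed one-degree-of-freedom chi-square statistic to its null median
#' (0.4549).
#'
#' @param statistics Vector of nonnegative chi-square statistics.
#' @return The inflation factor lambda (unfloored).
#' @export
gc_lambda <- function(statistics) {
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) == 0) abort("no finite statistics supplied")
  if (any(statistics < 0)) abort("chi-square statistics must be nonnegative")
  median(statistics) / qchisq(0.5, 1)
}

#' Apply genomic control to a chi-square statistic
#'
#' Divides by `max(1, lambda)`: deflation only, never inflation.
#'
#' @param statistic Observed 1-df chi-square statistic(s).
#' @param lambda Inflation factor from [gc_lambda()].
#' @return Corrected statistic(s).
#' @export
gc_correct <- function(statistic, lambda) {
  statistic / max(1, lambda)
}

# Wald chi-square for the slope of a logistic regression of status on a
# single score, via glm.fit for speed.
wald_chisq <- function(score, status) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, score), status, family = binomial())
  )
  # Wald z^2 from the usual XtWX information
  w <- fit$weights
  xtx <- crossprod(cbind(1, score) * sqrt(w))
  se2 <- solve(xtx)[2, 2]
  unname(coef(fit)[2]^2 / se2)
}

#' Case-control test of GP with permutation-calibrated genomic control
#'
#' Because the leave-pair-out plan overfits, the Wald chi-square of the
#' case-control GP contrast is inflated under the null. This test
#' recomputes GP under `n_perm` within-pair phenotype permutations (each
#' pair's labels flipped with probability 1/2, GP fully re-estimated
#' through the leave-pair-out machinery), estimates the genomic-control
#' factor from the permutation null, and deflates the observed statistic.
#'
#' @inheritParams leave_pair_out_gp
#' @param n_perm Number of within-pair permutations (default 200).
#' @param seed Seed for the permutation stream.
#' @return One-row tibble: observed chi-square, permutation `lambda`,
#'   GC-corrected chi-square and p-value, and the uncorrected p.
#' @export
gp_case_control_test <- function(grm, pairs, subjects, h2 = 0.70,
                                 n_perm = 200, seed = 1L) {
  eng <- lpo_engine(grm, pairs, h2)
  y <- phenotype_for(subjects, eng$ids)
  gp_obs <- standardize(drop(eng$predict(y)))
  chi_obs <- wald_chisq(gp_obs, y)

  set.seed(derive_seed(seed, "permutation"))
  npairs <- eng$n / 2
  flips <- matrix(runif(npairs * n_perm) < 0.5, npairs, n_perm)
  yperm <- matrix(y, eng$n, n_perm)
  for (b in seq_len(n_perm)) {
    fl <- rep(flips[, b], each = 2)
    idx <- seq_len(eng$n)
    swapped <- idx + ifelse(idx %% 2 == 1, 1L, -1L)  # partner within pair
    yperm[fl, b] <- y[swapped[fl]]
  }
  gperm <- eng$predict(yperm)
  chi_perm <- vapply(seq_len(n_perm), function(b) {
    g <- gperm[, b]
    s <- stats::sd(g)
    if (!is.finite(s) || s == 0) return(0)
    wald_chisq((g - mean(g)) / s, yperm[, b])
  }, numeric(1))
  lam <- gc_lambda(chi_perm)
  chi_corr <- gc_correct(chi_obs, lam)
  tibble(
    chisq = chi_obs,
    p = pchisq(chi_obs, 1, lower.tail = FALSE),
    lambda = lam,
    chisq_gc = chi_corr,
    p_gc = pchisq(chi_corr, 1, lower.tail = FALSE),
    n_perm = n_perm
  )
}
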