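#' Logistic evaluation of a standardized score
#'
#' Maximum-likelihood logistic regression of case status on a single
#' standardized score. Reports the odds ratio per SD of score with its
#' Wald 95% CI and p-value, and Nagelkerke's pseudo-R-squared
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`. Complete separation is flagged
#' and reported with an infinite-OR sentinel rather than an error.
#'
#' @param score Numeric standardized score (or a `score_vector` tibble, in
#'   which case its `score` column is used, aligned by `subject_id` if
#'   `status` is a tibble).
#' @param status 0/1 case status vector, or tibble with `subject_id` and
#'   `status`.
#' @return A `score_eval` object; see [glance.score_eval()].
#' @export
evaluate_score <- function(score, status) {
  if (inherits(score, "score_vector") || (is.data.frame(score))) {
    sdf <- as_tibble(score)
    if (is.data.frame(status)) {
      status <- as_tibble(status)
      y <- status$status[match(sdf$subject_id, status$subject_id)]
    } else {
      y <- status
    }
    s <- sdf$score
  } else {
    s <- score
    y <- if (is.data.frame(status)) as_tibble(status)$status else status
  }
  y <- as.numeric(y)
  stopifnot(length(s) == length(y))
  keep <- is.finite(s) & is.finite(y)
  s <- s[keep]; y <- y[keep]
  if (length(unique(y)) < 2) abort("both statuses must be present")
  if (stats::sd(s) == 0) abort("score is constant; odds ratio undefined")
  n <- length(y)

  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ s, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  beta <- coef(fit)[["s"]]
  if (abs(beta) > 15) sep <- TRUE
  se <- sqrt(vcov(fit)["s", "s"])
  ll1 <- as.numeric(logLik(fit))
  ll0 <- as.numeric(logLik(glm(y ~ 1, family = binomial())))
  r2 <- (1 - exp(2 / n * (ll0 - ll1))) / (1 - exp(2 / n * ll0))
  r2 <- min(max(r2, 0), 1)
  or <- exp(beta)
  if (sep) or <- sign(beta) * Inf
  structure(
    list(
      or = or, beta = beta, se = se,
      ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
      p = 2 * pnorm(-abs(beta / se)),
      pseudo_r2 = r2, n = n, separation = sep
    ),
    class = "score_eval"
  )
}

#' @export
print.score_eval <- function(x, ...) {
  cat(sprintf("Logistic score evaluation (n = %d)%s\n", x$n,
              if (x$separation) "  [complete separation]" else ""))
  cat(sprintf("  OR per SD   %.3f  (95%% CI %.3f-%.3f)\n",
              x$or, x$ci[1], x$ci[2]))
  cat(sprintf("  P           %.3g\n", x$p))
  cat(sprintf("  pseudo-R2   %.2f%%\n", 100 * x$pseudo_r2))
  invisible(x)
}

#' @rdname evaluate_score
#' @param x A `score_eval`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.score_eval <- function(x, ...) {
  tibble(term = "score", estimate = x$beta, std.error = x$se,
         or = x$or, conf.low = x$ci[1], conf.high = x$ci[2], p.value = x$p)
}

#' @rdname evaluate_score
#' @exportS3Method generics::glance
glance.score_eval <- function(x, ...) {
  tibble(or = x$or, conf.low = x$ci[1], conf.high = x$ci[2], p.value = x$p,
         pseudo_r2 = x$pseudo_r2, n = x$n, separation = x$separation)
}

#' Weights for the weighted genomic risk score
#'
#' Under the `pseudoR2` scheme each component's weight is its Nagelkerke
#' pseudo-R-squared divided by the components' sum; the `equal` scheme
#' gives `1/k`.
#'
#' @param pseudo_r2 Named numeric vector of component pseudo-R-squared
#'   values (any common scale).
#' @param scheme `"pseudoR2"` or `"equal"`.
#' @return Tibble `component`, `pseudo_r2`, `weight` (weights sum to 1).
#' @export
wgrs_weights <- function(pseudo_r2, scheme = c("pseudoR2", "equal")) {
  scheme <- match.arg(scheme)
  k <- length(pseudo_r2)
  nm <- names(pseudo_r2) %||% paste0("score", seq_len(k))
  w <- if (scheme == "equal") rep(1 / k, k) else {
    if (sum(pseudo_r2) <= 0) {
      warn("all pseudo-R2 are zero; falling back to equal weights")
      rep(1 / k, k)
    } else pseudo_r2 / sum(pseudo_r2)
  }
  tibble(component = nm, pseudo_r2 = as.numeric(pseudo_r2),
         weight = as.numeric(w), scheme = scheme)
}

#' Combine standardized scores into a weighted genomic risk score
#'
#' Evaluates each component against case status, weights the components by
#' their Nagelkerke pseudo-R-squared (or equally), forms the weighted sum,
#' and standardizes the result to mean 0, SD 1. Weighting on the same
#' sample being analyzed follows the reference design and is optimistically
#' biased; pass an independent `weight_on` subset of subjects for a
#' split-sample variant.
#'
#' @param components Named list of `score_vector` tibbles covering the same
#'   subjects.
#' @param status Tibble with `subject_id` and `status`, or 0/1 vector in
#'   component order.
#' @param scheme `"pseudoR2"` (default) or `"equal"`.
#' @param weight_on Optional character vector of subject ids on which to
#'   compute the weights (split-sample mode); scoring still covers all
#'   subjects.
#' @return A list with `score` (the WGRS `score_vector`) and `weights`
#'   (the [wgrs_weights()] tibble).
#' @export
combine_wgrs <- function(components, status, scheme = c("pseudoR2", "equal"),
                         weight_on = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(is.list(components), length(components) >= 1)
  nm <- names(components) %||% paste0("score", seq_along(components))
  ids <- as_tibble(components[[1]])$subject_id
  mat <- vapply(components, function(cc) {
    cc <- as_tibble(cc)
    s <- cc$score[match(ids, cc$subject_id)]
    if (anyNA(s)) abort("components must cover the same subjects")
    s
  }, numeric(length(ids)))
  colnames(mat) <- nm
  y <- if (is.data.frame(status)) {
    as_tibble(status)$status[match(ids, as_tibble(status)$subject_id)]
  } else status
  stopifnot(length(y) == length(ids))

  widx <- if (is.null(weight_on)) seq_along(ids) else match(weight_on, ids)
  r2 <- vapply(nm, function(j) {
    evaluate_score(mat[widx, j], y[widx])$pseudo_r2
  }, numeric(1))
  w <- wgrs_weights(r2, scheme)
  raw <- drop(mat %*% w$weight)
  list(
    score = new_score(
      tibble(subject_id = ids, score = standardize(raw), raw = raw),
      name = "WGRS",
      provenance = sprintf("weighted combination (%s) of %s", scheme,
                           paste(nm, collapse = ", "))),
    weights = w
  )
}

#' Polygenic transmission disequilibrium test
#'
#' For complete trios, the deviation of each child's score from the
#' midparent mean, scaled by the standard deviation of the midparent
#' scores, is tested against zero mean with a one-sample t-test. Under
#' random transmission the expected deviation is zero; over-transmission
#' of polygenic risk to ascertained cases shifts it positive.
#'
#' @param trios Tibble with columns `child`, `mother`, `father` (scores),
#'   e.g. from [simulate_trio_scores()]. Alternatively pass three numeric
#'   vectors via `child`, `mother`, `father`.
#' @param child,mother,father Optional numeric vectors used when `trios`
#'   is missing.
#' @return One-row tibble: `mean_deviation`, `t`, `df`, `p.value`, `n`.
#' @export
ptdt <- function(trios = NULL, child = NULL, mother = NULL, father = NULL) {
  if (!is.null(trios)) {
    trios <- as_tibble(trios)
    child <- trios$child; mother <- trios$mother; father <- trios$father
  }
  stopifnot(length(child) == length(mother),
            length(child) == length(father))
  ok <- complete.cases(child, mother, father)
  child <- child[ok]; mother <- mother[ok]; father <- father[ok]
  if (length(child) < 2) abort("need at least 2 complete trios")
  mid <- (mother + father) / 2
  s <- stats::sd(mid)
  if (!is.finite(s) || s == 0) abort("midparent scores have zero variance")
  dev <- (child - mid) / s
  n <- length(dev)
  if (stats::sd(dev) < 1e-12) {
    # degenerate but well-defined: every child sits exactly at the same
    # deviation; the t statistic is 0 when that deviation is 0
    tstat <- if (abs(mean(dev)) < 1e-12) 0 else Inf * sign(mean(dev))
    return(tibble(mean_deviation = mean(dev), t = tstat, df = n - 1,
                  p.value = if (tstat == 0) 1 else 0, n = n))
  }
  tt <- t.test(dev, mu = 0)
  tibble(mean_deviation = mean(dev), t = unname(tt$statistic),
         df = unname(tt$parameter), p.value = tt$p.value, n = length(dev))
}

#' Group contrasts of a genomic score by diagnosis and carrier status
#'
#' Mean score with seeded percentile-bootstrap 95% CIs for controls, all
#' cases, carrier cases, non-carrier cases, and carrier cases by most
#' severe PDV class; plus the logistic odds ratio of carrier status on the
#' score among cases only. Undetermined subjects are excluded from the
#' carrier/non-carrier contrasts but retained as cases in the case-control
#' groups.
#'
#' @param score A `score_vector` tibble (`subject_id`, `score`).
#' @param subjects Tibble with `subject_id` and `status`.
#' @param calls Carrier calls from [classify_carriers()].
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @return A `burden_contrasts` object: `groups` tibble (group, n, mean,
#'   conf.low, conf.high) and `carrier_or` ([glance.score_eval()] row), or
#'   `NULL` when a carrier group is empty.
#' @export
burden_contrasts <- function(score, subjects, calls, n_boot = 2000,
                             seed = 1L) {
  score <- as_tibble(score)
  subjects <- as_tibble(subjects)
  calls <- as_tibble(calls)
  df <- score |>
    left_join(subjects[, c("subject_id", "status")], by = "subject_id") |>
    left_join(calls[, c("subject_id", "status", "most_severe")],
              by = "subject_id", suffix = c("", "_carrier")) |>
    rename(carrier_status = "status_carrier")
  set.seed(derive_seed(seed, "bootstrap"))
  boot_ci <- function(x) {
    if (length(x) < 2) return(c(NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot), function(b) {
      mean(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  grp <- list(
    controls = df$score[df$status == 0],
    cases = df$score[df$status == 1],
    carrier_cases = df$score[df$status == 1 &
                               df$carrier_status %in% "carrier"],
    noncarrier_cases = df$score[df$status == 1 &
                                  df$carrier_status %in% "non-carrier"]
  )
  for (cls in c("CNV", "PTV", "MIS")) {
    grp[[paste0("carrier_", cls)]] <-
      df$score[df$status == 1 & df$most_severe %in% cls]
  }
  empty <- vapply(grp, length, integer(1)) == 0
  if (any(empty)) {
    warn(paste("empty groups omitted:", paste(names(grp)[empty], collapse = ", ")))
    grp <- grp[!empty]
  }
  groups <- imap(grp, function(x, nm) {
    ci <- boot_ci(x)
    tibble(group = nm, n = length(x), mean = mean(x),
           conf.low = ci[1], conf.high = ci[2])
  }) |> list_rbind()

  cases_det <- df[df$status == 1 &
                    df$carrier_status %in% c("carrier", "non-carrier"), ]
  carrier_or <- if (length(unique(cases_det$carrier_status)) == 2) {
    tryCatch(
      glance(evaluate_score(cases_det$score,
                            as.integer(cases_det$carrier_status == "carrier"))),
      error = function(e) {
        warn(paste("carrier contrast skipped:", conditionMessage(e)))
        NULL
      })
  } else NULL
  structure(list(groups = groups, carrier_or = carrier_or),
            class = "burden_contrasts")
}

#' @export
print.burden_contrasts <- function(x, ...) {
  cat("Score means by group (bootstrap 95% CI):\n")
  print(x$groups)
  if (!is.null(x$carrier_or)) {
    cat("\nCarrier vs non-carrier (cases only), logistic OR per SD:\n")
    print(x$carrier_or)
  }
  invisible(x)
}

#' @rdname burden_contrasts
#' @param x A `burden_contrasts`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.burden_contrasts <- function(x, ...) x$groups
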