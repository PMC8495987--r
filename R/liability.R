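#' Liability threshold from prevalence
#'
#' Under the liability-threshold model, liability is standard normal in the
#' population and a subject is affected exactly when liability exceeds a
#' threshold `t` set by the population prevalence `K`.
#'
#' @param K Population prevalence, in (0, 1).
#' @return The threshold `t = qnorm(1 - K)`, in liability standard deviations.
#' @examples
#' threshold_from_prevalence(0.5)    # 0
#' threshold_from_prevalence(0.015)  # ~2.17
#' @export
threshold_from_prevalence <- function(K) {
  check_prob(K, "K")
  qnorm(1 - K)
}

#' Mean liability of affected and unaffected subjects
#'
#' Truncated-normal means of a standard normal liability above and below the
#' prevalence threshold: `mean_affected = phi(t)/K` and
#' `mean_unaffected = -phi(t)/(1 - K)`, where `phi` is the standard normal
#' density. The two means satisfy the law of total expectation,
#' `K * mean_affected + (1 - K) * mean_unaffected = 0`.
#'
#' @inheritParams threshold_from_prevalence
#' @return A tibble with columns `K`, `threshold`, `mean_affected`,
#'   `mean_unaffected`, `half_distance` (half the distance between the two
#'   group means).
#' @examples
#' group_means(0.015)  # affected ~2.525, unaffected ~-0.038
#' @export
group_means <- function(K) {
  check_prob(K, "K")
  t <- threshold_from_prevalence(K)
  ma <- dnorm(t) / K
  mu <- -dnorm(t) / (1 - K)
  tibble(
    K = K, threshold = t,
    mean_affected = ma, mean_unaffected = mu,
    half_distance = (ma - mu) / 2
  )
}

#' Mean-liability shift implied by a carrier risk ratio
#'
#' Finds the shift `delta` such that carriers of a rare damaging variant,
#' whose liability is `Normal(delta, 1)`, exceed the population threshold
#' with the probability implied by a rho-fold excess risk. Two risk scales
#' are supported: `"risk_ratio"` takes carrier risk `K_c = rho * K`;
#' `"odds_ratio"` applies rho to the disease odds,
#' `K_c = rho * Omega / (1 + rho * Omega)` with `Omega = K / (1 - K)`.
#' The two parametrizations differ appreciably once `rho * K` is not small:
#' at `K = 0.015`, `rho = 15` the odds scale gives `delta ~ 1.277` while the
#' risk scale gives `delta ~ 1.415`.
#'
#' @inheritParams threshold_from_prevalence
#' @param rho Excess risk of carriers relative to non-carriers, > 0.
#' @param risk_scale `"odds_ratio"` (default) or `"risk_ratio"`.
#' @return The carrier shift `delta = t - qnorm(1 - K_c)`, in liability SD.
#' @examples
#' carrier_shift(0.015, 15)                  # ~1.277
#' carrier_shift(0.015, 15, "risk_ratio")    # ~1.415
#' carrier_shift(0.1, 1)                     # 0
#' @export
carrier_shift <- function(K, rho, risk_scale = c("odds_ratio", "risk_ratio")) {
  check_prob(K, "K")
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0) {
    abort("`rho` must be a positive number")
  }
  risk_scale <- match.arg(risk_scale)
  Kc <- switch(risk_scale,
    risk_ratio = rho * K,
    odds_ratio = {
      omega <- K / (1 - K)
      rho * omega / (1 + rho * omega)
    }
  )
  if (Kc >= 1) {
    abort(sprintf("implied carrier risk %.3f is >= 1; reduce `rho`", Kc))
  }
  threshold_from_prevalence(K) - qnorm(1 - Kc)
}

#' Build a liability-threshold model
#'
#' Bundles the full analytic calculus for one prevalence and one carrier
#' risk ratio: the diagnosis threshold, the truncated-normal group means of
#' affected and unaffected subjects, the carrier shift `delta`, and the
#' half-distance between group means.
#'
#' @inheritParams carrier_shift
#' @return An object of class `liability_model`; see [tidy.liability_model()].
#' @examples
#' m <- liability_model(K = 0.015, rho = 15)
#' glance(m)
#' @export
liability_model <- function(K, rho, risk_scale = c("odds_ratio", "risk_ratio")) {
  risk_scale <- match.arg(risk_scale)
  gm <- group_means(K)
  delta <- carrier_shift(K, rho, risk_scale)
  structure(
    list(
      K = K, rho = rho, risk_scale = risk_scale,
      threshold = gm$threshold,
      mean_affected = gm$mean_affected,
      mean_unaffected = gm$mean_unaffected,
      half_distance = gm$half_distance,
      midpoint = (gm$mean_affected + gm$mean_unaffected) / 2,
      carrier_shift = delta
    ),
    class = "liability_model"
  )
}

#' @export
print.liability_model <- function(x, ...) {
  cat("Liability-threshold model\n")
  cat(sprintf("  prevalence K            %.4g\n", x$K))
  cat(sprintf("  threshold t             %.4f\n", x$threshold))
  cat(sprintf("  mean liability affected %.4f\n", x$mean_affected))
  cat(sprintf("  mean liability unaff.   %.4f\n", x$mean_unaffected))
  cat(sprintf("  half-distance           %.4f\n", x$half_distance))
  cat(sprintf("  arithmetic midpoint     %.4f\n", x$midpoint))
  cat(sprintf("  carrier shift delta     %.4f  (rho = %g, %s scale)\n",
              x$carrier_shift, x$rho, x$risk_scale))
  invisible(x)
}

#' @rdname liability_model
#' @param x A `liability_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.liability_model <- function(x, ...) {
  tibble(
    quantity = c("threshold", "mean_affected", "mean_unaffected",
                 "half_distance", "midpoint", "carrier_shift"),
    value = c(x$threshold, x$mean_affected, x$mean_unaffected,
              x$half_distance, x$midpoint, x$carrier_shift)
  )
}

#' @rdname liability_model
#' @exportS3Method generics::glance
glance.liability_model <- function(x, ...) {
  tibble(
    K = x$K, rho = x$rho, risk_scale = x$risk_scale,
    threshold = x$threshold, mean_affected = x$mean_affected,
    mean_unaffected = x$mean_unaffected, half_distance = x$half_distance,
    midpoint = x$midpoint, carrier_shift = x$carrier_shift
  )
}

#' Position observed score means against the liability calculus
#'
#' Compares observed group means of a standardized genomic score (affected,
#' unaffected, affected carriers) with the analytic liability calculus.
#' Because "mid-point" admits two readings, the report carries both
#' conventions side by side: the arithmetic midpoint `(a + u)/2` of the two
#' group means, and the half-distance `(a - u)/2` between them. The observed
#' carrier mean is additionally placed on the normalized `[0, 1]` interval
#' running from the unaffected mean to the affected mean, where exact
#' additivity of rare and common risk puts a carrier group below 1 in
#' proportion to the liability already conferred by the rare variant.
#'
#' @param model A [liability_model()].
#' @param observed_means Named numeric vector or list with entries
#'   `affected`, `unaffected`, `affected_carriers` on the score scale.
#' @return A tibble with one row per convention: the analytic value, the
#'   observed carrier position, and the normalized position in `[0, 1]`.
#' @examples
#' m <- liability_model(0.015, 15)
#' additivity_diagnostics(m, c(affected = 0.256, unaffected = -0.256,
#'                             affected_carriers = 0.045))
#' @export
additivity_diagnostics <- function(model, observed_means) {
  stopifnot(inherits(model, "liability_model"))
  om <- as.list(observed_means)
  need <- c("affected", "unaffected", "affected_carriers")
  if (!all(need %in% names(om))) {
    abort(paste("`observed_means` needs entries:", paste(need, collapse = ", ")))
  }
  a <- om$affected; u <- om$unaffected; cc <- om$affected_carriers
  span <- a - u
  pos_obs <- (cc - u) / span
  pos_delta <- (model$carrier_shift - model$mean_unaffected) /
    (model$mean_affected - model$mean_unaffected)
  tibble(
    convention = c("half_distance", "arithmetic_midpoint"),
    analytic_liability = c(model$half_distance, model$midpoint),
    carrier_shift = model$carrier_shift,
    observed_carrier_mean = cc,
    observed_midpoint = c(span / 2, (a + u) / 2),
    normalized_carrier_position = pos_obs,
    normalized_delta_position = pos_delta
  )
}

#' Liability density sketch for a fitted model
#'
#' Draws the population liability density with the diagnosis threshold and
#' the group means (unaffected, affected, carrier shift) marked, mirroring
#' the conventional liability-threshold figure.
#'
#' @param object A [liability_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.liability_model <- function(object, ...) {
  x <- seq(-4, 4.5, length.out = 400)
  df <- tibble(liability = x, density = dnorm(x))
  marks <- tibble(
    value = c(object$mean_unaffected, object$carrier_shift,
              object$mean_affected, object$threshold),
    label = c("unaffected mean", "carrier shift", "affected mean", "threshold")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$liability, y = .data$density)) +
    ggplot2::geom_area(data = ~ dplyr::filter(.x, .data$liability > object$threshold),
                       fill = "firebrick", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$value,
                                     linetype = .data$label)) +
    ggplot2::labs(x = "liability (SD)", y = "density", linetype = NULL)
}
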