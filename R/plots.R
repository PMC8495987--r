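#' Score distributions by diagnosis and carrier status
#'
#' Violin/boxplot of a standardized genomic score across controls,
#' non-carrier cases and carrier cases — the conventional burden-by-group
#' figure.
#'
#' @param score A `score_vector` tibble.
#' @param subjects Tibble with `subject_id` and `status`.
#' @param calls Optional carrier calls from [classify_carriers()]; when
#'   omitted only case/control groups are drawn.
#' @return A ggplot object.
#' @export
plot_score_groups <- function(score, subjects, calls = NULL) {
  df <- as_tibble(score) |>
    left_join(as_tibble(subjects)[, c("subject_id", "status")],
              by = "subject_id")
  df$group <- ifelse(df$status == 1, "case", "control")
  if (!is.null(calls)) {
    calls <- as_tibble(calls)
    cs <- calls$status[match(df$subject_id, calls$subject_id)]
    df$group <- dplyr::case_when(
      df$status == 0 ~ "control",
      cs %in% "carrier" ~ "case, PDV carrier",
      cs %in% "non-carrier" ~ "case, no PDV",
      TRUE ~ "case, undetermined"
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score,
                                   fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.5) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = paste(attr(score, "name") %||% "score",
                                      "(SD units)")) +
    ggplot2::theme(legend.position = "none")
}

#' Ancestry eigenvector scatter colored by cluster
#'
#' @param object A clustered `ancestry_space`.
#' @param dims Which two eigenvectors to plot (default 1:2).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ancestry_space <- function(object, dims = c(1, 2), ...) {
  df <- tidy(object)
  ev <- paste0("EV", dims)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ev[1]]],
                                        y = .data[[ev[2]]]))
  if ("cluster" %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster),
                                 size = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8)
  }
  p
}

#' Group means with bootstrap intervals
#'
#' @param object A `burden_contrasts`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.burden_contrasts <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf.low,
                                        ymax = .data$conf.high),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "mean score (SD units)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
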