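#' Classify subjects as carriers of potentially damaging variants
#'
#' A potentially damaging variant (PDV) is a protein-truncating variant
#' (PTV) in a risk gene, a missense variant in a risk gene with composite
#' deleteriousness score MPC strictly greater than 2, or a CNV flagged as
#' damaging. Subjects with a trisomy, or with large or multiple CNVs, cannot
#' be scored reliably and are set to `undetermined`. Every other subject is
#' a `carrier` if they have at least one qualifying PDV, with the most
#' severe class recorded under the severity ranking CNV > PTV > MIS, and a
#' `non-carrier` otherwise. Subjects with no variant records at all are
#' assumed non-carriers; the `assayed` column marks them for sensitivity
#' analyses.
#'
#' @param records Tibble/data.frame of variant records with columns
#'   `subject_id`, `gene`, `class` (one of PTV, MIS, CNV, TRISOMY), `mpc`
#'   (numeric, required for MIS, NA otherwise), `cnv_damaging` and
#'   `cnv_large_or_multiple` (logical, used for CNV rows).
#' @param subject_ids Character vector of all subjects to call (subjects
#'   without records are allowed and called non-carriers).
#' @param risk_genes Character vector of risk-gene symbols (e.g. the 102
#'   ASD risk genes); must be non-empty.
#' @return A tibble with one row per subject: `subject_id`, `status`
#'   (carrier / non-carrier / undetermined), `most_severe` (CNV/PTV/MIS or
#'   NA), `assayed` (had at least one record).
#' @examples
#' recs <- tibble::tibble(
#'   subject_id = c("s1", "s2"), gene = c("GENE1", "GENE1"),
#'   class = c("PTV", "MIS"), mpc = c(NA, 1.5),
#'   cnv_damaging = FALSE, cnv_large_or_multiple = FALSE)
#' classify_carriers(recs, c("s1", "s2", "s3"), "GENE1")
#' @export
classify_carriers <- function(records, subject_ids, risk_genes) {
  if (length(risk_genes) == 0) abort("`risk_genes` must be non-empty")
  subject_ids <- as.character(subject_ids)
  records <- as_tibble(records)
  needed <- c("subject_id", "gene", "class")
  if (!all(needed %in% names(records))) {
    abort(paste("`records` must have columns:", paste(needed, collapse = ", ")))
  }
  if (!"mpc" %in% names(records)) records$mpc <- NA_real_
  if (!"cnv_damaging" %in% names(records)) records$cnv_damaging <- FALSE
  if (!"cnv_large_or_multiple" %in% names(records)) {
    records$cnv_large_or_multiple <- FALSE
  }
  bad_class <- setdiff(unique(records$class), c("PTV", "MIS", "CNV", "TRISOMY"))
  if (length(bad_class) > 0) {
    abort(paste("malformed variant class:", paste(bad_class, collapse = ", ")))
  }
  unknown <- setdiff(unique(records$subject_id), subject_ids)
  if (length(unknown) > 0) {
    abort(paste("records reference unknown subjects:",
                paste(head(unknown, 5), collapse = ", ")))
  }

  severity <- c(CNV = 3, PTV = 2, MIS = 1)
  per <- records |>
    mutate(
      qualifying = (.data$class == "PTV" & .data$gene %in% risk_genes) |
        (.data$class == "MIS" & .data$gene %in% risk_genes &
           !is.na(.data$mpc) & .data$mpc > 2) |
        (.data$class == "CNV" & .data$cnv_damaging %in% TRUE),
      undet = .data$class == "TRISOMY" | .data$cnv_large_or_multiple %in% TRUE
    ) |>
    group_by(.data$subject_id) |>
    summarise(
      undetermined = any(.data$undet),
      any_pdv = any(.data$qualifying),
      best = if (any(.data$qualifying)) {
        qcls <- .data$class[.data$qualifying]
        qcls[which.max(severity[qcls])]
      } else NA_character_,
      .groups = "drop"
    )

  calls <- tibble(subject_id = subject_ids) |>
    left_join(per, by = "subject_id") |>
    mutate(
      assayed = !is.na(.data$undetermined),
      status = dplyr::case_when(
        .data$undetermined %in% TRUE ~ "undetermined",
        .data$any_pdv %in% TRUE ~ "carrier",
        TRUE ~ "non-carrier"
      ),
      most_severe = ifelse(.data$status == "carrier", .data$best, NA_character_)
    ) |>
    select("subject_id", "status", "most_severe", "assayed")
  calls
}

#' Tabulate carrier calls by most severe PDV class
#'
#' @param calls Output of [classify_carriers()].
#' @return A tibble counting subjects in each of CNV, PTV, MIS (carriers by
#'   most severe class), non-carrier, and undetermined.
#' @export
severity_table <- function(calls) {
  calls <- as_tibble(calls)
  key <- ifelse(calls$status == "carrier", calls$most_severe, calls$status)
  lev <- c("CNV", "PTV", "MIS", "non-carrier", "undetermined")
  tibble(
    group = lev,
    n = unname(vapply(lev, function(l) sum(key == l, na.rm = TRUE),
                      integer(1)))
  )
}
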