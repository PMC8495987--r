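# Readers/writers for the interchange formats: PLINK 1 binary genotypes,
# a simple dosage-TSV dialect, and the GCTA binary GRM triplet.

#' Write genotypes as a PLINK 1 binary fileset
#'
#' Writes `.bed` (SNP-major, magic 0x6c 0x1b 0x01), `.bim` and `.fam`.
#' Dosages count copies of allele `a1`; 2 is encoded as homozygous A1
#' (bits 00), 1 as heterozygous (10), 0 as homozygous A2 (11) and NA as
#' missing (01).
#'
#' @param genotypes A `genotype_matrix` (subjects x variants).
#' @param prefix Output path prefix (no extension).
#' @param phenotype Optional 0/1 status vector written to the .fam (PLINK
#'   codes 1 = control, 2 = case; default -9 missing).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, phenotype = NULL) {
  v <- variants(genotypes)
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  ids <- rownames(genotypes) %||% sprintf("S%d", seq_len(n))
  pheno <- if (is.null(phenotype)) rep(-9L, n) else as.integer(phenotype) + 1L
  readr::write_tsv(
    tibble(fid = ids, iid = ids, pat = 0L, mat = 0L, sex = 0L, pheno = pheno),
    paste0(prefix, ".fam"), col_names = FALSE)
  readr::write_tsv(
    tibble(chr = v$chr, id = v$variant_id, cm = 0, pos = v$pos,
           a1 = v$a1, a2 = v$a2),
    paste0(prefix, ".bim"), col_names = FALSE)

  # 2-bit codes per subject, 4 subjects per byte, padded per variant
  code <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # dosage of a1 -> PLINK code
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  nbytes <- ceiling(n / 4)
  for (j in seq_len(m)) {
    x <- genotypes[, j]
    cd <- ifelse(is.na(x), 1L, code[as.character(x)])
    cd <- c(cd, rep(0L, nbytes * 4 - n))
    byte <- cd[seq(1, length(cd), 4)] +
      cd[seq(2, length(cd), 4)] * 4L +
      cd[seq(3, length(cd), 4)] * 16L +
      cd[seq(4, length(cd), 4)] * 64L
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}

#' Read a PLINK 1 binary fileset
#'
#' @param prefix Path prefix of a `.bed`/`.bim`/`.fam` trio.
#' @return A list with `genotypes` (a `genotype_matrix`, dosage of the
#'   .bim A1 allele) and `fam` (tibble of the .fam columns).
#' @export
read_plink <- function(prefix) {
  fam <- readr::read_tsv(paste0(prefix, ".fam"), col_names =
    c("fid", "iid", "pat", "mat", "sex", "pheno"), show_col_types = FALSE)
  bim <- readr::read_tsv(paste0(prefix, ".bim"), col_names =
    c("chr", "variant_id", "cm", "pos", "a1", "a2"), show_col_types = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a SNP-major PLINK .bed file")
  }
  body <- as.integer(raw[-(1:3)])
  nbytes <- ceiling(n / 4)
  # expand each byte into four 2-bit codes
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, (body %/% 64L) %% 4L)
  dim(codes) <- c(4 * nbytes, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  dose <- matrix(NA_integer_, n, m)
  dose[codes == 0L] <- 2L
  dose[codes == 2L] <- 1L
  dose[codes == 3L] <- 0L
  vt <- tibble(variant_id = bim$variant_id, chr = bim$chr, pos = bim$pos,
               a1 = bim$a1, a2 = bim$a2)
  list(genotypes = new_genotype_matrix(dose, fam$iid, vt), fam = fam)
}

#' Write genotypes as a dosage TSV
#'
#' First column `subject_id`, then one column per variant named by variant
#' id, values in \{0, 1, 2, NA\}; variant metadata goes to
#' `<path>.variants.tsv`.
#'
#' @inheritParams write_plink
#' @param path Output TSV path.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  v <- variants(genotypes)
  df <- as_tibble(as.data.frame(unclass(genotypes)))
  names(df) <- v$variant_id
  df <- bind_cols(tibble(subject_id = rownames(genotypes)), df)
  readr::write_tsv(df, path)
  readr::write_tsv(v, paste0(path, ".variants.tsv"))
  invisible(path)
}

#' Read a dosage TSV written by [write_dosage_tsv()]
#' @param path TSV path.
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  ids <- df$subject_id
  x <- as.matrix(df[, -1, drop = FALSE])
  vpath <- paste0(path, ".variants.tsv")
  vt <- if (file.exists(vpath)) {
    readr::read_tsv(vpath, show_col_types = FALSE)
  } else {
    tibble(variant_id = colnames(x), chr = 1L, pos = seq_len(ncol(x)),
           a1 = "A", a2 = "B")
  }
  new_genotype_matrix(x, ids, vt)
}

#' Write a GRM in GCTA binary triplet format
#'
#' Writes `.grm.bin` (float32 lower triangle, row-major by subject),
#' `.grm.N.bin` (float32 variant counts) and `.grm.id`.
#'
#' @param grm A `grm` object from [compute_grm()].
#' @param prefix Output path prefix.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$matrix)
  lower <- grm$matrix[upper.tri(grm$matrix, diag = TRUE)]
  # GCTA order: for j in 1..n, entries (j, 1..j) — i.e. column-wise upper
  # triangle of the symmetric matrix equals row-wise lower triangle
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(lower), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(rep(as.numeric(grm$m_variants), length(lower)), con, size = 4)
  close(con)
  readr::write_tsv(tibble(fid = grm$ids, iid = grm$ids),
                   paste0(prefix, ".grm.id"), col_names = FALSE)
  invisible(prefix)
}

#' Read a GCTA binary GRM triplet
#' @param prefix Path prefix of `.grm.bin`/`.grm.N.bin`/`.grm.id`.
#' @param mode Standardization label to attach (not stored in the format).
#' @return A `grm` object.
#' @export
read_grm_gcta <- function(prefix, mode = "STD") {
  ids <- readr::read_tsv(paste0(prefix, ".grm.id"),
                         col_names = c("fid", "iid"), show_col_types = FALSE)
  n <- nrow(ids)
  nl <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = nl, size = 4)
  nvar <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = nl, size = 4)
  a <- matrix(0, n, n)
  a[upper.tri(a, diag = TRUE)] <- vals
  a <- a + t(a) - diag(diag(a))
  new_grm(a, ids$iid, mode = mode, m_variants = round(nvar[1]))
}

#' Write a GRM as plain TSV (id, id, value)
#' @inheritParams write_grm_gcta
#' @param path Output TSV path.
#' @export
write_grm_tsv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  idx <- which(upper.tri(grm$matrix, diag = TRUE), arr.ind = TRUE)
  readr::write_tsv(tibble(
    id1 = grm$ids[idx[, 1]], id2 = grm$ids[idx[, 2]],
    value = grm$matrix[idx]
  ), path)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits genotypes (PLINK binary or dosage TSV), a subject table TSV
#' (`id, cohort, status, cluster, carrier_flag`) and a truth table TSV.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"plink"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("plink", "tsv")) {
  stopifnot(inherits(cohort, "sim_cohort"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "plink") {
    write_plink(cohort$genotypes, file.path(dir, "genotypes"),
                phenotype = cohort$subjects$status)
  } else {
    write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  }
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
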