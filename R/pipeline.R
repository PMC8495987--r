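#' Synthetic PDV variant records for a simulated cohort
#'
#' Translates the simulator's carrier flags into per-subject variant
#' annotation records against a synthetic risk-gene set, so the carrier
#' classifier can be exercised end-to-end: each carrier receives one
#' qualifying record (damaging CNV, PTV, or missense with MPC > 2, drawn
#' with the given class mix), and a small fraction of subjects receive a
#' large/multiple-CNV record making them undetermined.
#'
#' @param subjects Cohort subject tibble with `subject_id` and
#'   `carrier_flag`.
#' @param risk_genes Synthetic risk-gene symbols (default 102 genes).
#' @param class_mix Probabilities for CNV/PTV/MIS among carriers.
#' @param undetermined_rate Probability a subject is rendered undetermined.
#' @param seed Integer seed.
#' @return A variant-record tibble for [classify_carriers()].
#' @export
simulate_pdv_records <- function(subjects,
                                 risk_genes = sprintf("RG%03d", 1:102),
                                 class_mix = c(CNV = 0.2, PTV = 0.5, MIS = 0.3),
                                 undetermined_rate = 0.01,
                                 seed = 1L) {
  subjects <- as_tibble(subjects)
  set.seed(derive_seed(seed, "carriers"))
  carriers <- subjects$subject_id[subjects$carrier_flag]
  cls <- sample(names(class_mix), length(carriers), replace = TRUE,
                prob = class_mix)
  recs <- tibble(
    subject_id = carriers,
    gene = sample(risk_genes, length(carriers), replace = TRUE),
    class = cls,
    mpc = ifelse(cls == "MIS", runif(length(carriers), 2.01, 5), NA_real_),
    cnv_damaging = cls == "CNV",
    cnv_large_or_multiple = FALSE
  )
  und <- subjects$subject_id[runif(nrow(subjects)) < undetermined_rate]
  if (length(und) > 0) {
    recs <- bind_rows(recs, tibble(
      subject_id = und, gene = sample(risk_genes, length(und), replace = TRUE),
      class = "CNV", mpc = NA_real_, cnv_damaging = FALSE,
      cnv_large_or_multiple = TRUE
    ))
  }
  recs
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full joint-liability analysis pipeline
#'
#' Orchestrates simulate (or load) -> ancestry -> GRM -> leave-pair-out
#' G-BLUP -> P+T PRS -> WGRS -> carrier calls -> liability calculus, and
#' writes every artifact plus a machine-readable summary and a Markdown
#' report to `out_dir`.
#'
#' @param config Named list (or path to a YAML/JSON file) with a mandatory
#'   `seed`, exactly one of `simulation` (arguments to [sim_config()]) or
#'   `input` (list with `genotypes` PLINK prefix or `dosage_tsv` path, and
#'   `subjects` TSV path), and optional module blocks `ancestry`
#'   (`d`, `k`, `window`, `step`, `r2_max`), `gblup` (`h2`, `n_perm`),
#'   `prs` (`p_threshold`, `clump_r2`, `clump_window_kb`), `wgrs`
#'   (`scheme`), `carriers` (`records` TSV path, `risk_genes` path),
#'   `liability` (`prevalence`, `rho`, `risk_scale`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with every stage's objects and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) abort("config error: `seed` is required")
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input) {
    abort("config error: exactly one of `simulation` or `input` must be given")
  }
  seed <- as.integer(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  anc_cfg <- utils::modifyList(
    list(d = 3, k = NULL, window = 50, step = 5, r2_max = 0.64),
    config$ancestry %||% list())
  gb_cfg <- utils::modifyList(list(h2 = 0.70, n_perm = 200),
                              config$gblup %||% list())
  prs_cfg <- utils::modifyList(
    list(p_threshold = 0.01, clump_r2 = 0.1, clump_window_kb = 250),
    config$prs %||% list())
  wgrs_cfg <- utils::modifyList(list(scheme = "pseudoR2"),
                                config$wgrs %||% list())
  liab_cfg <- utils::modifyList(
    list(prevalence = 0.015, rho = 15, risk_scale = "odds_ratio"),
    config$liability %||% list())

  # --- data ----------------------------------------------------------------
  if (has_sim) {
    cohort <- pipeline_stage("simulate", {
      cfg <- do.call(sim_config, utils::modifyList(config$simulation,
                                                   list(seed = seed)))
      simulate_cohort(cfg)
    })
    write_cohort(cohort, file.path(out_dir, "data"))
    genotypes <- cohort$genotypes
    subjects <- cohort$subjects
  } else {
    dat <- pipeline_stage("load", {
      g <- if (!is.null(config$input$dosage_tsv)) {
        read_dosage_tsv(config$input$dosage_tsv)
      } else {
        read_plink(config$input$genotypes)$genotypes
      }
      s <- readr::read_tsv(config$input$subjects, show_col_types = FALSE)
      list(g = g, s = s)
    })
    cohort <- NULL
    genotypes <- dat$g
    subjects <- dat$s
  }
  analysis_ids <- subjects$subject_id[subjects$cohort != "pool_control"]
  pool_ids <- subjects$subject_id[subjects$cohort == "pool_control"]
  if (length(pool_ids) == 0) {
    abort("config error: cohort contains no pool_control subjects for frequency estimation")
  }

  # --- ancestry ------------------------------------------------------------
  anc <- pipeline_stage("ancestry", {
    pruned <- ld_prune(genotypes, anc_cfg$window, anc_cfg$step, anc_cfg$r2_max)
    space <- compute_eigenvectors(genotypes, pruned, d = anc_cfg$d)
    space <- cluster_subjects(space, k = anc_cfg$k, seed = seed)
    pairs <- match_pairs(space, subjects[subjects$subject_id %in% analysis_ids,
                                         c("subject_id", "status")])
    list(pruned = pruned, space = space, pairs = pairs)
  })
  readr::write_tsv(tidy(anc$space), file.path(out_dir, "ancestry_space.tsv"))
  readr::write_tsv(as_tibble(anc$pairs), file.path(out_dir, "pairs.tsv"))

  # --- GRM -----------------------------------------------------------------
  grm_obj <- pipeline_stage("grm", {
    pool_idx <- match(pool_ids, rownames(genotypes))
    pool_geno <- new_genotype_matrix(unclass(genotypes)[pool_idx, , drop = FALSE],
                                     pool_ids, variants(genotypes))
    pool_cl <- anc$space$clusters[match(pool_ids, anc$space$ids)]
    freqs <- estimate_frequencies(pool_geno, pool_cl)
    an_idx <- match(analysis_ids, rownames(genotypes))
    an_geno <- new_genotype_matrix(unclass(genotypes)[an_idx, , drop = FALSE],
                                   analysis_ids, variants(genotypes))
    an_cl <- anc$space$clusters[match(analysis_ids, anc$space$ids)]
    grm <- compute_grm(an_geno, mode = "CLS", frequencies = freqs,
                       clusters = an_cl)
    list(freqs = freqs, grm = grm, pool_geno = pool_geno,
         analysis_geno = an_geno)
  })
  write_grm_gcta(grm_obj$grm, file.path(out_dir, "grm_cls"))

  # --- G-BLUP GP -----------------------------------------------------------
  gp <- pipeline_stage("gblup", {
    score <- leave_pair_out_gp(grm_obj$grm, anc$pairs, subjects,
                               h2 = gb_cfg$h2)
    test <- gp_case_control_test(grm_obj$grm, anc$pairs, subjects,
                                 h2 = gb_cfg$h2, n_perm = gb_cfg$n_perm,
                                 seed = seed)
    list(score = score, test = test)
  })
  readr::write_tsv(as_tibble(gp$score), file.path(out_dir, "gp.tsv"))

  # --- PRS -----------------------------------------------------------------
  prs <- pipeline_stage("prs", {
    make_prs <- function(stats, name) {
      aligned <- align_alleles(stats, genotypes)
      idx <- clump(aligned, grm_obj$pool_geno, prs_cfg$clump_r2,
                   prs_cfg$clump_window_kb, prs_cfg$p_threshold)
      prs_score(grm_obj$analysis_geno, aligned, idx, name = name)
    }
    if (has_sim) {
      # two independent training cohorts stand in for external GWAS
      train_stats <- function(off) {
        tcfg <- cohort$config
        tcfg$seed <- as.integer((seed + off) %% .Machine$integer.max)
        tc <- simulate_cohort(tcfg)
        simulate_summary_stats(tc$genotypes, tc$subjects$status)
      }
      list(asd = make_prs(train_stats(1000L), "ASD-PRS"),
           scz = make_prs(train_stats(2000L), "SCZ-PRS"))
    } else if (!is.null(config$prs$summary_stats)) {
      stats_paths <- config$prs$summary_stats
      setNames(
        lapply(names(stats_paths), function(nm) {
          make_prs(readr::read_tsv(stats_paths[[nm]], show_col_types = FALSE),
                   nm)
        }),
        names(stats_paths))
    } else {
      list()
    }
  })
  for (nm in names(prs)) {
    readr::write_tsv(as_tibble(prs[[nm]]),
                     file.path(out_dir, paste0("prs_", tolower(nm), ".tsv")))
  }

  # --- WGRS ----------------------------------------------------------------
  comps <- c(list(GP = gp$score), prs)
  wgrs <- pipeline_stage("wgrs", {
    combine_wgrs(comps, subjects, scheme = wgrs_cfg$scheme)
  })
  readr::write_tsv(as_tibble(wgrs$score), file.path(out_dir, "wgrs.tsv"))

  # --- carriers ------------------------------------------------------------
  carr <- pipeline_stage("carriers", {
    src <- if (!is.null(config$carriers$records)) {
      list(recs = readr::read_tsv(config$carriers$records,
                                  show_col_types = FALSE),
           genes = readr::read_lines(config$carriers$risk_genes))
    } else if (has_sim) {
      genes <- sprintf("RG%03d", 1:102)
      list(recs = simulate_pdv_records(subjects, risk_genes = genes,
                                       seed = seed),
           genes = genes)
    } else NULL
    if (is.null(src)) NULL else {
      calls <- classify_carriers(src$recs, subjects$subject_id, src$genes)
      list(records = src$recs, calls = calls,
           severity = severity_table(calls))
    }
  })
  if (!is.null(carr)) {
    readr::write_tsv(carr$calls, file.path(out_dir, "carrier_calls.tsv"))
  }

  # --- evaluation ----------------------------------------------------------
  an_status <- subjects[match(c(rbind(anc$pairs$case_id, anc$pairs$control_id)),
                              subjects$subject_id), c("subject_id", "status")]
  evals <- pipeline_stage("evaluate", {
    res <- imap(comps, function(sc, nm) {
      glance(evaluate_score(sc, an_status)) |>
        mutate(score = nm, .before = 1)
    }) |> list_rbind()
    w <- glance(evaluate_score(wgrs$score, an_status)) |>
      mutate(score = "WGRS", .before = 1)
    bind_rows(res, w)
  })
  readr::write_tsv(evals, file.path(out_dir, "evaluation.tsv"))

  contrasts <- if (!is.null(carr)) {
    pipeline_stage("contrasts", {
      burden_contrasts(wgrs$score, an_status, carr$calls, seed = seed)
    })
  } else NULL

  # --- liability -----------------------------------------------------------
  liab <- pipeline_stage("liability", {
    model <- liability_model(liab_cfg$prevalence, liab_cfg$rho,
                             liab_cfg$risk_scale)
    diag <- if (!is.null(contrasts)) {
      gm <- contrasts$groups
      pick <- function(g) gm$mean[match(g, gm$group)]
      om <- c(affected = pick("cases"), unaffected = pick("controls"),
              affected_carriers = pick("carrier_cases"))
      if (anyNA(om)) NULL else additivity_diagnostics(model, om)
    } else NULL
    list(model = model, diagnostics = diag)
  })

  summary <- list(
    seed = seed,
    n_subjects = nrow(subjects),
    n_pairs = nrow(anc$pairs),
    n_clusters = anc$space$n_clusters,
    n_pruned_variants = length(anc$pruned),
    grm = list(mode = grm_obj$grm$mode, m_variants = grm_obj$grm$m_variants,
               eb_prior_strength = grm_obj$freqs$prior_m,
               fst_hat = grm_obj$freqs$fhat),
    gp_test = as.list(gp$test),
    evaluation = evals,
    wgrs_weights = wgrs$weights,
    severity = if (!is.null(carr)) carr$severity else NULL,
    group_means = if (!is.null(contrasts)) contrasts$groups else NULL,
    liability = as.list(glance(liab$model)),
    additivity = liab$diagnostics
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       dataframe = "columns")
  write_report(summary, file.path(out_dir, "report.md"))
  writeLines(yaml::as.yaml(list(seed = seed, ancestry = anc_cfg,
                                gblup = gb_cfg, prs = prs_cfg,
                                wgrs = wgrs_cfg, liability = liab_cfg,
                                simulation = config$simulation)),
             file.path(out_dir, "run_parameters.yaml"))

  invisible(list(cohort = cohort, subjects = subjects, ancestry = anc,
                 frequencies = grm_obj$freqs, grm = grm_obj$grm, gp = gp,
                 prs = prs, wgrs = wgrs, carriers = carr,
                 evaluation = evals, contrasts = contrasts,
                 liability = liab, summary = summary))
}

write_report <- function(summary, path) {
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "f")
  lines <- c(
    "# Joint common/rare variant liability analysis",
    "",
    sprintf("Seed %d; %d subjects, %d matched pairs, %d ancestry clusters.",
            summary$seed, summary$n_subjects, summary$n_pairs,
            summary$n_clusters),
    "",
    "## Score evaluation (case vs control)",
    "",
    "| Score | OR per SD | 95% CI | P | pseudo-R2 (%) |",
    "|---|---|---|---|---|",
    vapply(seq_len(nrow(summary$evaluation)), function(i) {
      e <- summary$evaluation[i, ]
      sprintf("| %s | %s | %s-%s | %.2g | %s |", e$score, fmt(e$or, 2),
              fmt(e$conf.low, 2), fmt(e$conf.high, 2), e$p.value,
              fmt(100 * e$pseudo_r2, 2))
    }, character(1)),
    "",
    sprintf("GP case-control Wald chi-square %s; genomic-control lambda %s; corrected chi-square %s (P = %.2g).",
            fmt(summary$gp_test$chisq, 2), fmt(summary$gp_test$lambda, 3),
            fmt(summary$gp_test$chisq_gc, 2), summary$gp_test$p_gc),
    "",
    "## Liability calculus",
    "",
    sprintf("Prevalence %s sets the threshold at %s; mean liability %s (affected) and %s (unaffected); half-distance %s; carrier shift %s (%s scale).",
            fmt(summary$liability$K, 3), fmt(summary$liability$threshold),
            fmt(summary$liability$mean_affected),
            fmt(summary$liability$mean_unaffected),
            fmt(summary$liability$half_distance),
            fmt(summary$liability$carrier_shift),
            summary$liability$risk_scale)
  )
  if (!is.null(summary$severity)) {
    lines <- c(lines, "", "## Carrier calls (most severe class)", "",
               vapply(seq_len(nrow(summary$severity)), function(i) {
                 sprintf("- %s: %d", summary$severity$group[i],
                         summary$severity$n[i])
               }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}
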