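#' LD pruning by moving-window pairwise r-squared
#'
#' Greedy moving-window pruning of variants: within each window of
#' `window` variants (ordered by chromosome and position), any pair whose
#' squared Pearson correlation of dosages exceeds `r2_max` loses its
#' later-positioned member; the window then advances by `step` variants.
#' The retained set contains no within-window pair with r-squared above the
#' threshold. Monomorphic variants have undefined r-squared; they are
#' skipped in the correlation computation and therefore always retained.
#'
#' @param genotypes A `genotype_matrix`.
#' @param window Window size in variants (default 50).
#' @param step Window advance in variants (default 5).
#' @param r2_max Maximum allowed squared correlation (default 0.64).
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(genotypes, window = 50, step = 5, r2_max = 0.64) {
  window <- check_count(window, "window")
  step <- check_count(step, "step")
  if (window < step) abort("`window` must be >= `step`")
  if (!is.numeric(r2_max) || r2_max <= 0 || r2_max > 1) {
    abort("`r2_max` must lie in (0, 1]")
  }
  v <- variants(genotypes)
  ord <- order(v$chr, v$pos, v$variant_id)
  x <- unclass(genotypes)[, ord, drop = FALSE]
  m <- ncol(x)
  keep <- rep(TRUE, m)
  sds <- apply(x, 2, stats::sd)
  poly <- sds > 0

  starts <- seq(1, max(1, m - 1), by = step)
  for (s in starts) {
    idx <- which(keep)
    idx <- idx[idx >= s & idx < s + window]
    idx <- idx[poly[idx]]
    if (length(idx) < 2) next
    repeat {
      r2 <- suppressWarnings(cor(x[, idx, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      hit <- which(r2 > r2_max, arr.ind = TRUE)
      if (nrow(hit) == 0) break
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      # first offending pair in scan order; drop the later-positioned member
      first <- hit[order(hit[, 1], hit[, 2])[1], ]
      drop_at <- idx[first[2]]
      keep[drop_at] <- FALSE
      idx <- setdiff(idx, drop_at)
      if (length(idx) < 2) break
    }
  }
  v$variant_id[ord][keep]
}

#' Ancestry eigenvectors from a standard GRM
#'
#' Eigendecomposition of the tool-default (STD-mode) GRM restricted to a
#' variant subset, typically an LD-pruned set. The top `d` eigenvectors are
#' scaled to unit norm and given a deterministic sign: the coordinate of
#' largest magnitude in each eigenvector is positive.
#'
#' @param genotypes A `genotype_matrix`.
#' @param variant_ids Variant subset to use (default: all variants).
#' @param d Number of eigenvectors to keep (default 3).
#' @return An `ancestry_space` (eigenvectors, eigenvalues, subject ids;
#'   cluster labels unset until [cluster_subjects()]).
#' @export
compute_eigenvectors <- function(genotypes, variant_ids = NULL, d = 3) {
  d <- check_count(d, "d")
  v <- variants(genotypes)
  if (is.null(variant_ids)) variant_ids <- v$variant_id
  if (length(variant_ids) == 0) abort("variant subset is empty")
  sub <- genotypes[, match(variant_ids, v$variant_id), drop = FALSE]
  sub <- new_genotype_matrix(unclass(sub), rownames(genotypes),
                             v[match(variant_ids, v$variant_id), ])
  grm <- compute_grm(sub, mode = "STD")
  e <- eigen(grm$matrix, symmetric = TRUE)
  rank <- sum(e$values > 1e-8 * max(abs(e$values)))
  if (d > rank) {
    abort(sprintf("requested d = %d eigenvectors but GRM rank is %d", d, rank))
  }
  vec <- e$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  rownames(vec) <- rownames(genotypes)
  colnames(vec) <- paste0("EV", seq_len(d))
  structure(
    list(vectors = vec, values = e$values[seq_len(d)],
         ids = rownames(genotypes), clusters = NULL, n_clusters = NULL),
    class = "ancestry_space"
  )
}

#' @export
print.ancestry_space <- function(x, ...) {
  cat(sprintf("<ancestry_space: %d subjects, %d eigenvectors%s>\n",
              length(x$ids), ncol(x$vectors),
              if (is.null(x$clusters)) "" else
                sprintf(", %d clusters", x$n_clusters)))
  invisible(x)
}

#' @rdname compute_eigenvectors
#' @param x An `ancestry_space`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ancestry_space <- function(x, ...) {
  out <- bind_cols(tibble(subject_id = x$ids), as_tibble(x$vectors))
  if (!is.null(x$clusters)) out$cluster <- x$clusters
  out
}

#' Cluster subjects in eigenvector space
#'
#' k-means on the eigenvector coordinates with deterministic seeding.
#' When `k` is `NULL` it is chosen as the value in `2..8` maximizing the
#' average silhouette width. Cluster labels are relabeled in descending
#' cluster size.
#'
#' @param space An `ancestry_space` from [compute_eigenvectors()].
#' @param k Number of clusters, or `NULL` to select by silhouette.
#' @param seed Seed for the k-means initialization.
#' @return The `ancestry_space` with `clusters` (factor) and `n_clusters`
#'   filled in.
#' @export
cluster_subjects <- function(space, k = NULL, seed = 1L) {
  stopifnot(inherits(space, "ancestry_space"))
  n <- length(space$ids)
  run_km <- function(k) {
    set.seed(derive_seed(seed, "clustering"))
    kmeans(space$vectors, centers = k, nstart = 10, iter.max = 100)
  }
  if (is.null(k)) {
    dd <- dist(space$vectors)
    ks <- 2:min(8, n - 1)
    sil <- vapply(ks, function(kk) {
      cl <- run_km(kk)$cluster
      mean(cluster::silhouette(cl, dd)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- check_count(k, "k")
  if (k > n) abort("`k` cannot exceed the number of subjects")
  lab <- if (k == 1) rep(1L, n) else run_km(k)$cluster
  # relabel by descending size (stable for ties)
  sizes <- tabulate(lab, nbins = k)
  remap <- integer(k)
  remap[order(-sizes, seq_len(k))] <- seq_len(k)
  lab <- remap[lab]
  space$clusters <- factor(paste0("C", lab), levels = paste0("C", seq_len(k)))
  space$n_clusters <- k
  space
}

# Jonker-Volgenant shortest-augmenting-path solver for the rectangular
# linear assignment problem; cost must have nrow <= ncol. Returns the
# assigned column for each row. O(n^2 m).
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n)
  v <- numeric(m + 1)
  p <- integer(m + 1)        # p[j]: row matched to column j (0 = free)
  way <- integer(m + 1)
  virt <- m + 1L
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(m)) {
        if (used[j]) next
        cur <- cost[i0, j] - u[i0] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) ans[p[j]] <- j
  ans
}

#' Genetically matched case-control pairs
#'
#' Within each ancestry cluster, pairs cases with controls by
#' minimum-total-distance optimal 1:1 assignment, distances being Euclidean
#' in the eigenvector space. Leftover controls are reported unmatched;
#' clusters holding cases but no controls leave those cases unmatched with
#' a warning.
#'
#' @param space A clustered `ancestry_space`.
#' @param subjects Tibble with `subject_id` and `status` (1 = case,
#'   0 = control) covering the subjects to match; exclude any
#'   frequency-estimation pool beforehand.
#' @return A `matched_pairs` object: tibble of pairs (`case_id`,
#'   `control_id`, `distance`, `cluster`) with attributes
#'   `unmatched_controls`, `unmatched_cases` and `mean_distance`.
#' @export
match_pairs <- function(space, subjects) {
  stopifnot(inherits(space, "ancestry_space"))
  if (is.null(space$clusters)) abort("cluster subjects before matching")
  subjects <- as_tibble(subjects)
  stopifnot(all(c("subject_id", "status") %in% names(subjects)))
  miss <- setdiff(subjects$subject_id, space$ids)
  if (length(miss) > 0) abort("subjects absent from ancestry space")

  pos <- space$vectors[match(subjects$subject_id, space$ids), , drop = FALSE]
  cl <- space$clusters[match(subjects$subject_id, space$ids)]
  pairs <- list()
  unmatched_controls <- character(0)
  unmatched_cases <- character(0)
  for (lev in levels(droplevels(cl))) {
    in_cl <- which(cl == lev)
    cases <- in_cl[subjects$status[in_cl] == 1]
    ctrls <- in_cl[subjects$status[in_cl] == 0]
    if (length(cases) == 0) {
      unmatched_controls <- c(unmatched_controls, subjects$subject_id[ctrls])
      next
    }
    if (length(ctrls) == 0) {
      warn(sprintf("cluster %s has %d cases but no controls; left unmatched",
                   lev, length(cases)))
      unmatched_cases <- c(unmatched_cases, subjects$subject_id[cases])
      next
    }
    dmat <- as.matrix(dist(pos[c(cases, ctrls), , drop = FALSE]))
    dmat <- dmat[seq_along(cases), length(cases) + seq_along(ctrls),
                 drop = FALSE]
    if (length(cases) <= length(ctrls)) {
      asg <- solve_assignment(dmat)
      matched_cases <- seq_along(cases)
      matched_ctrls <- asg
    } else {
      asg <- solve_assignment(t(dmat))
      matched_cases <- asg
      matched_ctrls <- seq_along(ctrls)
      unmatched_cases <- c(unmatched_cases,
                           subjects$subject_id[cases[-asg]])
    }
    pairs[[length(pairs) + 1]] <- tibble(
      case_id = subjects$subject_id[cases[matched_cases]],
      control_id = subjects$subject_id[ctrls[matched_ctrls]],
      distance = dmat[cbind(matched_cases, matched_ctrls)],
      cluster = lev
    )
    if (length(ctrls) > length(cases)) {
      unmatched_controls <- c(unmatched_controls,
                              subjects$subject_id[ctrls[-matched_ctrls]])
    }
  }
  out <- if (length(pairs) > 0) bind_rows(pairs) else
    tibble(case_id = character(0), control_id = character(0),
           distance = numeric(0), cluster = character(0))
  structure(out,
            unmatched_controls = unmatched_controls,
            unmatched_cases = unmatched_cases,
            mean_distance = if (nrow(out) > 0) mean(out$distance) else NA_real_,
            class = c("matched_pairs", class(out)))
}

#' @export
print.matched_pairs <- function(x, ...) {
  cat(sprintf("<matched_pairs: %d pairs, mean distance %.4g; %d unmatched controls, %d unmatched cases>\n",
              nrow(x), attr(x, "mean_distance"),
              length(attr(x, "unmatched_controls")),
              length(attr(x, "unmatched_cases"))))
  NextMethod()
}
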