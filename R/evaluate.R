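# Leave-one-out cross-validation and robustness experiments.
#
# Caching layout: a fold only changes the held-out disease's propagation
# vector, so per-disease fold score vectors are computed once and reused by
# every experiment that merely changes the phenotype matrix (ablation,
# permutation) or the disease subset (subsampling).

#' Mann-Whitney AUC from positive ranks
#'
#' `AUC = P(random positive outranks random negative)`, computed from the
#' (possibly fractional mid-)ranks of the positives in the joint candidate
#' list, rank 1 = best:
#' `AUC = 1 - (sum(ranks) - n_pos (n_pos + 1) / 2) / (n_pos * n_neg)`.
#' Ties between a positive and negatives enter through midranks and count
#' one half.
#'
#' @param positive_ranks Numeric vector of (mid)ranks of the positives.
#' @param n_candidates Total candidates (positives + negatives).
#' @param n_positives Number of positives (default `length(positive_ranks)`).
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_from_ranks(3, 10)  # one positive at rank 3 of 10 -> 7/9
#' @export
auc_from_ranks <- function(positive_ranks, n_candidates,
                           n_positives = length(positive_ranks)) {
  n_pos <- n_positives
  n_neg <- n_candidates - n_pos
  if (n_pos < 1L || n_neg < 1L)
    stop("AUC needs at least one positive and one negative", call. = FALSE)
  if (length(positive_ranks) != n_pos)
    stop("'positive_ranks' length disagrees with 'n_positives'", call. = FALSE)
  if (any(positive_ranks < 1) || any(positive_ranks > n_candidates))
    stop("ranks must lie in [1, n_candidates]", call. = FALSE)
  1 - (sum(positive_ranks) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC curve from scores
#'
#' Standard empirical ROC polygon: one vertex per distinct score threshold,
#' tied groups traversed diagonally. Trapezoidal integration of this polygon
#' equals the Mann-Whitney AUC with the half-tie convention, which the test
#' suite uses as a two-route consistency check.
#'
#' @param positive,negative Numeric score vectors (higher = more disease-like).
#' @return Data frame of polygon vertices with columns `fpr`, `tpr`.
#' @export
roc_points <- function(positive, negative) {
  if (length(positive) == 0L || length(negative) == 0L)
    stop("ROC needs at least one positive and one negative score",
         call. = FALSE)
  thr <- sort(unique(c(positive, negative)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(positive >= t), numeric(1L)))
  fpr <- c(0, vapply(thr, function(t) mean(negative >= t), numeric(1L)))
  data.frame(fpr = fpr, tpr = tpr)
}

#' Trapezoidal area under an ROC curve
#' @param roc Data frame from [roc_points()] (vertices ordered by `fpr`).
#' @return Area in `[0, 1]`.
#' @export
auc_trapezoid <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-n]) / 2)
}

# ---- internal evaluation machinery -------------------------------------

# Per-disease LOOCV fold propagation vectors over the candidate universe.
# For disease d with usable seeds s1..sm, row j holds the propagation of
# seeds minus s_j. Diseases with < 2 usable seeds get NULL (skipped).
loocv_fold_scores <- function(networks, seedsets, control,
                              universe = NULL) {
  if (is.null(universe))
    universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"),
                                   use.names = FALSE)))
  out <- list()
  for (d in names(networks)) {
    seeds <- intersect(if (is.null(seedsets[[d]])) character(0L)
                       else seedsets[[d]], universe)
    if (length(seeds) < 2L) { out[d] <- list(NULL); next }
    mat <- matrix(0, nrow = length(seeds), ncol = length(universe),
                  dimnames = list(seeds, universe))
    for (j in seq_along(seeds)) {
      sv <- suppressWarnings(
        rwr(networks[[d]], setdiff(seeds, seeds[j]),
            restart_prob = control$restart_prob, tol = control$rwr_tol,
            max_iter = control$rwr_max_iter, norm = control$norm))
      mat[j, names(sv)] <- sv
    }
    out[[d]] <- mat
  }
  out
}

# y-values of one fold's ROC polygon on the common FPR grid k/n_neg
# (vertical-averaging convention; used for the plotting curves only).
fold_tpr_grid <- function(u, t, n_neg) {
  k <- 0:n_neg
  if (t > 0) return(pmin(pmax((k - u) / t, 0), 1))
  y <- as.numeric(k > u)
  if (u > 0 && u < n_neg) y[k == u] <- 0.5
  if (u == 0) y[k == 0] <- 1
  y
}

# Core LOOCV scoring given cached base scores and fold vectors.
loocv_core <- function(S_base, folds, seedsets, P, control,
                       diseases = rownames(S_base), label = "primary",
                       with_roc = TRUE) {
  universe <- colnames(S_base)
  Psub <- P[diseases, diseases, drop = FALSE]
  if (isTRUE(control$row_normalize_P)) {
    rs <- rowSums(Psub); rs[rs == 0] <- 1
    Psub <- Psub / rs
  }
  Ssub <- S_base[diseases, , drop = FALSE]
  aucs <- c(); rocs <- list(); recs <- list(); skipped <- character(0L)
  for (d in diseases) {
    fm <- folds[[d]]
    if (is.null(fm)) { skipped <- c(skipped, d); next }
    seeds <- rownames(fm)
    neg_mask <- !(universe %in% seeds)
    n_neg <- sum(neg_mask)
    if (n_neg < 1L) { skipped <- c(skipped, d); next }
    cross <- as.vector(Psub[d, , drop = FALSE] %*% Ssub) -
      Psub[d, d] * Ssub[d, ]
    fold_auc <- numeric(length(seeds))
    grid <- matrix(0, nrow = length(seeds), ncol = n_neg + 1L)
    rec <- vector("list", length(seeds))
    for (j in seq_along(seeds)) {
      held <- seeds[j]
      sc <- cross + Psub[d, d] * fm[j, ]
      s_p <- sc[[held]]
      neg_sc <- sc[neg_mask]
      u <- sum(neg_sc > s_p)
      t <- sum(neg_sc == s_p)
      fold_auc[j] <- (n_neg - u - t / 2) / n_neg
      if (with_roc) grid[j, ] <- fold_tpr_grid(u, t, n_neg)
      neg_ids <- universe[neg_mask]
      rank_det <- u + sum(neg_sc == s_p & neg_ids < held) + 1L
      rec[[j]] <- data.frame(disease = d, held_out = held, rank = rank_det,
                             midrank = u + (t + 2) / 2, n_better = u,
                             n_tied = t, n_candidates = n_neg + 1L,
                             percentile = rank_det / (n_neg + 1L),
                             auc = fold_auc[j], stringsAsFactors = FALSE)
    }
    aucs[d] <- mean(fold_auc)
    if (with_roc)
      rocs[[d]] <- data.frame(fpr = (0:n_neg) / n_neg,
                              tpr = colMeans(grid))
    recs[[d]] <- do.call(rbind, rec)
  }
  if (length(aucs) == 0L)
    stop("no disease is evaluable (each needs >= 2 seeds in the candidate universe)",
         call. = FALSE)
  if (length(skipped) > 0L && identical(label, "primary"))
    warning("skipped disease(s) with < 2 usable seeds: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(label = label, auc = aucs, mean_auc = mean(aucs),
                 pooled_auc = mean(records$auc), records = records,
                 roc = rocs, skipped = skipped, control = control),
            class = "lncprop_eval")
}

identity_phenotype <- function(diseases) {
  P <- diag(length(diseases))
  dimnames(P) <- list(diseases, diseases)
  P
}

prep_eval <- function(networks, seedsets, P, control) {
  control <- as_control(control)
  stopifnot(is.list(networks), length(networks) >= 1L)
  diseases <- names(networks)
  missing <- setdiff(diseases, rownames(P))
  if (length(missing) > 0L)
    stop("disease(s) missing from the phenotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"),
                                 use.names = FALSE)))
  S_base <- score_table(networks, seedsets, control)
  folds <- loocv_fold_scores(networks, seedsets, control, universe)
  list(control = control, diseases = diseases, universe = universe,
       S_base = S_base, folds = folds, P = P, seedsets = seedsets)
}

# ---- user-facing experiments -------------------------------------------

#' Leave-one-out cross-validation of the prioritization
#'
#' For every disease with at least two seeds in the candidate universe, each
#' seed is held out in turn: the disease is re-propagated from the remaining
#' seeds, scores are re-integrated through the phenotype matrix, and the
#' held-out seed is ranked against all candidates that are not among the
#' disease's known seeds. Per-disease AUC is the Mann-Whitney AUC pooled
#' over the disease's folds (each fold contributes one positive against the
#' shared negative set); the headline figure is the arithmetic mean of the
#' per-disease AUCs, with the fold-pooled variant reported alongside.
#'
#' @param networks Named list of `competing_network` objects.
#' @param seedsets Named list of seed lncRNA vectors.
#' @param P Phenotype similarity matrix covering the diseases.
#' @param control A [lncprop_control()] object or list of overrides.
#' @return An object of class `"lncprop_eval"`: per-disease `auc`,
#'   `mean_auc`, `pooled_auc`, fold `records`, per-disease ROC point frames,
#'   skipped diseases, and the experiment `label`.
#' @export
loocv <- function(networks, seedsets = NULL, P = NULL,
                  control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    if (is.null(P)) P <- u$P
    control <- u$control
    networks <- u$networks
  }
  pe <- prep_eval(networks, seedsets, P, control)
  loocv_core(pe$S_base, pe$folds, pe$seedsets, pe$P, pe$control,
             label = "primary")
}

#' LOOCV without phenotype integration
#'
#' Identical to [loocv()] but with the phenotype matrix replaced by the
#' identity, so each disease relies on its own network and seeds only.
#'
#' @inheritParams loocv
#' @return A `"lncprop_eval"` object labelled `no_phenotype`.
#' @export
ablate_phenotype <- function(networks, seedsets = NULL,
                             control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    control <- u$control
    networks <- u$networks
  }
  control <- as_control(control)
  P <- identity_phenotype(names(networks))
  pe <- prep_eval(networks, seedsets, P, control)
  out <- loocv_core(pe$S_base, pe$folds, pe$seedsets, pe$P, pe$control,
                    label = "no_phenotype")
  out
}

permute_P <- function(P, scheme = c("offdiag", "rowwise")) {
  scheme <- match.arg(scheme)
  D <- nrow(P)
  if (scheme == "offdiag") {
    ut <- upper.tri(P)
    vals <- P[ut]
    Pp <- P
    Pp[ut] <- sample(vals)
    Pp[lower.tri(Pp)] <- t(Pp)[lower.tri(Pp)]
    Pp
  } else {
    Pp <- P
    for (i in seq_len(D)) {
      off <- setdiff(seq_len(D), i)
      Pp[i, off] <- sample(P[i, off])
    }
    (Pp + t(Pp)) / 2
  }
}

#' Phenotype-permutation control
#'
#' Repeatedly permutes the off-diagonal phenotype similarities (preserving
#' symmetry and the diagonal; scheme set by `control$permute`), reruns the
#' LOOCV, and records the mean AUC of each repetition. Fold propagation
#' vectors are computed once and reused, since only the integration step
#' depends on the phenotype matrix.
#'
#' @inheritParams loocv
#' @param reps Number of permutations (>= 1).
#' @return A list of class `"lncprop_dist"` with the per-repetition
#'   `mean_aucs`, their `mean`, and the experiment `label`.
#' @export
permute_phenotype <- function(networks, seedsets = NULL, P = NULL,
                              reps = 100L, control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    if (is.null(P)) P <- u$P
    control <- u$control
    networks <- u$networks
  }
  stopifnot(reps >= 1L)
  if (length(networks) < 3L)
    stop("phenotype permutation needs at least 3 diseases", call. = FALSE)
  pe <- prep_eval(networks, seedsets, P, control)
  if (!is.null(pe$control$rng_seed)) set.seed(pe$control$rng_seed)
  Psub <- P[pe$diseases, pe$diseases, drop = FALSE]
  vals <- vapply(seq_len(reps), function(i) {
    Pp <- permute_P(Psub, pe$control$permute)
    loocv_core(pe$S_base, pe$folds, pe$seedsets, Pp, pe$control,
               label = "permuted_phenotype", with_roc = FALSE)$mean_auc
  }, numeric(1L))
  structure(list(label = "permuted_phenotype", mean_aucs = vals,
                 mean = mean(vals), reps = reps),
            class = "lncprop_dist")
}

#' Random non-disease seed control
#'
#' Replaces every disease's seed set by an equal-size random draw from a
#' pool of non-disease lncRNAs, re-propagates and re-integrates, and scores
#' the ranks of the TRUE seeds (the evaluation positives stay the real known
#' disease lncRNAs; only the seeding is randomized). As everywhere else in
#' the evaluation, the current propagation seeds are excluded from the
#' candidate pool before ranking (in LOOCV the remaining true seeds play
#' that role; here the random replacement seeds do). A well-calibrated
#' method should fall to AUC ~ 0.5 under this control.
#'
#' @inheritParams loocv
#' @param pool Character vector of candidate lncRNAs with no known disease
#'   association; must be disjoint from every seed set and at least as large
#'   as the largest seed set.
#' @param reps Number of random draws.
#' @return A `"lncprop_dist"` object (per-repetition mean AUCs).
#' @export
random_seed_control <- function(networks, seedsets = NULL, P = NULL, pool,
                                reps = 100L, control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    if (is.null(P)) P <- u$P
    control <- u$control
    networks <- u$networks
  }
  stopifnot(reps >= 1L)
  control <- as_control(control)
  all_seeds <- unique(unlist(seedsets, use.names = FALSE))
  if (length(intersect(pool, all_seeds)) > 0L)
    stop("the non-disease pool must be disjoint from every seed set",
         call. = FALSE)
  sizes <- vapply(seedsets, length, integer(1L))
  if (length(pool) < max(sizes))
    stop("non-disease pool is smaller than the largest seed set",
         call. = FALSE)
  pe <- prep_eval(networks, seedsets, P, control)
  if (!is.null(pe$control$rng_seed)) set.seed(pe$control$rng_seed)
  universe <- pe$universe
  diseases <- pe$diseases
  Psub <- P[diseases, diseases, drop = FALSE]
  evaluable <- diseases[vapply(diseases, function(d) {
    length(intersect(seedsets[[d]], universe)) >= 2L &&
      sum(!(universe %in% seedsets[[d]])) >= 1L
  }, logical(1L))]
  if (length(evaluable) == 0L)
    stop("no disease is evaluable", call. = FALSE)
  vals <- numeric(reps)
  for (i in seq_len(reps)) {
    rand_seeds <- lapply(seedsets, function(s) sample(pool, length(s)))
    S <- suppressWarnings(score_table(networks, rand_seeds, control))
    SI <- Psub %*% S[diseases, , drop = FALSE]
    aucs <- vapply(evaluable, function(d) {
      pos <- intersect(seedsets[[d]], universe)
      neg_mask <- !(universe %in% seedsets[[d]]) &
        !(universe %in% rand_seeds[[d]])
      sc <- SI[d, ]
      neg_sc <- sc[neg_mask]
      n_neg <- length(neg_sc)
      fold <- vapply(pos, function(l) {
        u <- sum(neg_sc > sc[[l]]); t <- sum(neg_sc == sc[[l]])
        (n_neg - u - t / 2) / n_neg
      }, numeric(1L))
      mean(fold)
    }, numeric(1L))
    vals[i] <- mean(aucs)
  }
  structure(list(label = "random_seeds", mean_aucs = vals,
                 mean = mean(vals), reps = reps),
            class = "lncprop_dist")
}

#' Disease-count subsampling experiment
#'
#' Draws `k` diseases without replacement, restricts the phenotype matrix
#' and score table to them, reruns the LOOCV on the restricted corpus, and
#' repeats. Measures how much cross-disease evidence the integration gains
#' as more diseases participate.
#'
#' @inheritParams loocv
#' @param k Number of diseases per draw, `2 <= k <= D`.
#' @param reps Number of draws.
#' @return A `"lncprop_dist"` object labelled `subsample_k`.
#' @export
subsample_diseases <- function(networks, seedsets = NULL, P = NULL, k,
                               reps = 100L, control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    if (is.null(P)) P <- u$P
    control <- u$control
    networks <- u$networks
  }
  D <- length(networks)
  if (k < 2L || k > D)
    stop("'k' must lie in [2, number of diseases]", call. = FALSE)
  stopifnot(reps >= 1L)
  pe <- prep_eval(networks, seedsets, P, control)
  if (!is.null(pe$control$rng_seed)) set.seed(pe$control$rng_seed)
  vals <- numeric(reps)
  for (i in seq_len(reps)) {
    sel <- sample(pe$diseases, k)
    rep_i <- try(loocv_core(pe$S_base, pe$folds, pe$seedsets, pe$P,
                            pe$control, diseases = sel,
                            label = sprintf("subsample_%d", k),
                            with_roc = FALSE), silent = TRUE)
    vals[i] <- if (inherits(rep_i, "try-error")) NA_real_ else rep_i$mean_auc
  }
  structure(list(label = sprintf("subsample_%d", k),
                 mean_aucs = vals, mean = mean(vals, na.rm = TRUE),
                 reps = reps, k = k),
            class = "lncprop_dist")
}

#' Cross-disease-only prioritization
#'
#' Empties each disease's own propagation vector before integration, so its
#' candidates are scored purely from the other diseases' evidence weighted
#' by phenotype similarity. Every known seed of the disease becomes an
#' evaluation positive. Measures how far phenotype transfer alone carries a
#' disease with no usable seed information of its own.
#'
#' @inheritParams loocv
#' @return A `"lncprop_eval"` object labelled `cross_disease_only` (no ROC
#'   curves; fold records hold one row per known seed).
#' @export
cross_disease_only <- function(networks, seedsets = NULL, P = NULL,
                               control = lncprop_control()) {
  if (inherits(networks, "lncprop")) {
    u <- unpack_fit(networks)
    if (is.null(seedsets)) seedsets <- u$seeds
    if (is.null(P)) P <- u$P
    control <- u$control
    networks <- u$networks
  }
  if (length(networks) < 2L)
    stop("cross-disease prediction needs at least 2 diseases", call. = FALSE)
  pe <- prep_eval(networks, seedsets, P, control)
  diseases <- pe$diseases
  universe <- pe$universe
  Psub <- P[diseases, diseases, drop = FALSE]
  aucs <- c(); recs <- list(); skipped <- character(0L)
  for (d in diseases) {
    pos <- intersect(if (is.null(pe$seedsets[[d]])) character(0L)
                     else pe$seedsets[[d]], universe)
    if (length(pos) < 1L) { skipped <- c(skipped, d); next }
    cross <- as.vector(Psub[d, , drop = FALSE] %*% pe$S_base) -
      Psub[d, d] * pe$S_base[d, ]
    neg_mask <- !(universe %in% pos)
    n_neg <- sum(neg_mask)
    if (n_neg < 1L) { skipped <- c(skipped, d); next }
    neg_sc <- cross[neg_mask]
    rows <- lapply(pos, function(l) {
      u <- sum(neg_sc > cross[[l]]); t <- sum(neg_sc == cross[[l]])
      data.frame(disease = d, held_out = l,
                 rank = u + sum(neg_sc == cross[[l]] &
                                  universe[neg_mask] < l) + 1L,
                 midrank = u + (t + 2) / 2, n_better = u, n_tied = t,
                 n_candidates = n_neg + 1L,
                 percentile = (u + 1) / (n_neg + 1L),
                 auc = (n_neg - u - t / 2) / n_neg,
                 stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    aucs[d] <- mean(rows$auc)
    recs[[d]] <- rows
  }
  if (length(aucs) == 0L) stop("no disease is evaluable", call. = FALSE)
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(label = "cross_disease_only", auc = aucs,
                 mean_auc = mean(aucs), pooled_auc = mean(records$auc),
                 records = records, roc = list(), skipped = skipped,
                 control = pe$control),
            class = "lncprop_eval")
}

#' The non-disease candidate pool
#'
#' Candidate lncRNAs (network universe members) with no known disease
#' association in any seed set, usable by [random_seed_control()].
#'
#' @param networks Named list of `competing_network` objects.
#' @param seedsets Named list of seed vectors.
#' @return Character vector of lncRNA ids.
#' @export
non_disease_pool <- function(networks, seedsets = NULL) {
  if (inherits(networks, "lncprop")) {
    if (is.null(seedsets)) seedsets <- networks$seeds
    networks <- networks$networks
  }
  universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"),
                                 use.names = FALSE)))
  setdiff(universe, unique(unlist(seedsets, use.names = FALSE)))
}

#' @export
print.lncprop_eval <- function(x, ...) {
  cat(sprintf("Prioritization evaluation [%s]\n", x$label))
  cat(sprintf("  mean AUC over %d disease(s): %.4f (fold-pooled %.4f)\n",
              length(x$auc), x$mean_auc, x$pooled_auc))
  for (d in names(x$auc)) cat(sprintf("    %-12s AUC = %.4f\n", d, x$auc[d]))
  if (length(x$skipped) > 0L)
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lncprop_dist <- function(x, ...) {
  cat(sprintf("Evaluation distribution [%s]: %d repetition(s)\n",
              x$label, x$reps))
  cat(sprintf("  mean of mean AUCs = %.4f (sd %.4f)\n",
              x$mean, stats::sd(x$mean_aucs)))
  invisible(x)
}

#' Plot per-disease ROC curves of an evaluation
#' @param x A `"lncprop_eval"` object with ROC curves.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lncprop_eval <- function(x, ...) {
  if (length(x$roc) == 0L)
    stop("this evaluation holds no ROC curves", call. = FALSE)
  graphics::plot(c(0, 1), c(0, 1), type = "n", xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("LOOCV ROC [%s]", x$label), ...)
  graphics::abline(0, 1, lty = 3, col = "grey60")
  cols <- grDevices::hcl.colors(max(3L, length(x$roc)), "Dark 3")
  for (i in seq_along(x$roc))
    graphics::lines(x$roc[[i]]$fpr, x$roc[[i]]$tpr, col = cols[i], lwd = 1.5)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", names(x$roc),
                                    x$auc[names(x$roc)]),
                   col = cols[seq_along(x$roc)], lwd = 1.5, bty = "n",
                   cex = 0.8)
  invisible(x)
}
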