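#' Fit the network-propagation lncRNA prioritization model
#'
#' Runs the full pipeline: per disease, significant miRNA-lncRNA
#' co-expression is intersected with the validated interaction prior, the
#' lncRNA-lncRNA competing network is built from shared-partner
#' hypergeometric tests, known disease lncRNAs are propagated by random walk
#' with restart, and the per-disease score vectors are integrated across
#' diseases through the phenotype similarity matrix
#' (`S_ik = sum_j P_ij S_jk`).
#'
#' @param lncrna Named list of lncRNA expression matrices (one per disease),
#'   or a `"lncprop_corpus"` from [generate_corpus()] /
#'   [worked_fixture()] (in which case the remaining data arguments are
#'   taken from the corpus).
#' @param mirna Named list of miRNA expression matrices, same disease names
#'   and per-disease sample columns as `lncrna`.
#' @param interactions Validated [interaction_set()].
#' @param seeds Named list of seed lncRNA vectors per disease.
#' @param phenotype Disease phenotype similarity matrix covering the
#'   diseases.
#' @param control A [lncprop_control()] object or list of overrides.
#' @return An object of class `"lncprop"`: `networks` (per-disease
#'   `competing_network`), `scores` (disease x lncRNA propagation matrix),
#'   `integrated` (phenotype-integrated scores), `seeds`, `phenotype`,
#'   `universe`, `control`, `call`.
#' @seealso [predict.lncprop()] for ranked candidate lists, [loocv()] for
#'   evaluation.
#' @examples
#' fx <- worked_fixture()
#' fit <- lncprop(fx)
#' head(predict(fit, "D1"))
#' @export
lncprop <- function(lncrna, mirna = NULL, interactions = NULL, seeds = NULL,
                    phenotype = NULL, control = lncprop_control()) {
  cl <- match.call()
  if (inherits(lncrna, "lncprop_corpus")) {
    corpus <- lncrna
    lncrna <- corpus$lncrna; mirna <- corpus$mirna
    interactions <- corpus$interactions; seeds <- corpus$seeds
    phenotype <- corpus$phenotype
  }
  control <- as_control(control)
  diseases <- names(lncrna)
  if (is.null(diseases) || !identical(sort(diseases), sort(names(mirna))))
    stop("'lncrna' and 'mirna' must be named lists over the same diseases",
         call. = FALSE)
  networks <- stats::setNames(lapply(diseases, function(d) {
    suppressMessages(infer_network(mirna[[d]], lncrna[[d]], interactions,
                                   disease_id = d, control = control))
  }), diseases)
  fit <- lncprop_networks(networks, seeds, phenotype, control)
  fit$call <- cl
  fit
}

#' Fit the prioritization model from prebuilt competing networks
#'
#' Entry point when networks were inferred earlier (e.g. read back from edge
#' lists with [read_network()]): propagates the seeds and integrates across
#' diseases, skipping the co-expression stage.
#'
#' @param networks Named list of `competing_network` objects.
#' @param seeds Named list of seed lncRNA vectors.
#' @param phenotype Disease phenotype similarity matrix.
#' @param control A [lncprop_control()] object or list of overrides.
#' @return A `"lncprop"` object (see [lncprop()]).
#' @export
lncprop_networks <- function(networks, seeds, phenotype,
                             control = lncprop_control()) {
  control <- as_control(control)
  diseases <- names(networks)
  missing_P <- setdiff(diseases, rownames(phenotype))
  if (length(missing_P) > 0L)
    stop("disease(s) missing from the phenotype matrix: ",
         paste(missing_P, collapse = ", "), call. = FALSE)
  S <- score_table(networks, seeds, control)
  integrated <- integrate_scores(S, phenotype,
                                 row_normalize_P = control$row_normalize_P)
  structure(list(call = match.call(), networks = networks, scores = S,
                 integrated = integrated, seeds = seeds,
                 phenotype = phenotype[diseases, diseases, drop = FALSE],
                 universe = colnames(S), control = control),
            class = "lncprop")
}

unpack_fit <- function(fit) {
  list(networks = fit$networks, seeds = fit$seeds, P = fit$phenotype,
       control = fit$control)
}

#' @export
print.lncprop <- function(x, ...) {
  cat("Network-propagation lncRNA prioritization\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("%d disease(s), candidate universe of %d lncRNA(s)\n",
              length(x$networks), length(x$universe)))
  unseeded <- attr(x$scores, "unseeded")
  for (d in names(x$networks)) {
    n <- x$networks[[d]]
    cat(sprintf("  %-10s %4d nodes %5d edges  %d seed(s)%s\n", d,
                length(n$nodes), nrow(n$edges),
                length(x$seeds[[d]] %||% character(0L)),
                if (isTRUE(unseeded[d])) "  [unseeded]" else ""))
  }
  invisible(x)
}

#' @export
summary.lncprop <- function(object, top = 5L, ...) {
  tops <- lapply(rownames(object$integrated), function(d)
    utils::head(rank_candidates(object$integrated[d, ]), top))
  names(tops) <- rownames(object$integrated)
  structure(list(fit = object, top = tops), class = "summary.lncprop")
}

#' @export
print.summary.lncprop <- function(x, ...) {
  print(x$fit)
  cat("\nTop integrated candidates per disease:\n")
  for (d in names(x$top)) {
    cat(sprintf("  %s:\n", d))
    t <- x$top[[d]]
    for (i in seq_len(nrow(t)))
      cat(sprintf("    %2d. %-12s %.6g%s\n", t$rank[i], t$lncrna[i],
                  t$score[i],
                  if (t$lncrna[i] %in% x$fit$seeds[[d]]) "  (seed)" else ""))
  }
  invisible(x)
}

#' Integrated score matrix of a fitted prioritization
#' @param object A `"lncprop"` fit.
#' @param ... Unused.
#' @return Disease x lncRNA matrix of integrated scores `S_ik`.
#' @export
coef.lncprop <- function(object, ...) object$integrated

#' Ranked candidate lists from a fitted prioritization
#'
#' @param object A `"lncprop"` fit.
#' @param disease A disease id (default: all diseases, long format).
#' @param exclude_seeds Drop the disease's own known seeds from the
#'   candidate pool before ranking (default `FALSE`: known lncRNAs stay in
#'   the list, so their ranks can be reported).
#' @param top Keep only the best `top` candidates (default: all).
#' @param ... Unused.
#' @return For one disease, a data frame `(rank, lncrna, score)`; otherwise
#'   a long data frame with a leading `disease` column.
#' @export
predict.lncprop <- function(object, disease = NULL, exclude_seeds = FALSE,
                            top = NULL, ...) {
  one <- function(d) {
    excl <- if (exclude_seeds) object$seeds[[d]] %||% character(0L)
    else character(0L)
    r <- rank_candidates(object$integrated[d, ], exclude = excl)
    if (!is.null(top)) r <- utils::head(r, top)
    r
  }
  if (!is.null(disease)) {
    if (!disease %in% rownames(object$integrated))
      stop(sprintf("unknown disease '%s'", disease), call. = FALSE)
    return(one(disease))
  }
  do.call(rbind, lapply(rownames(object$integrated), function(d)
    cbind(disease = d, one(d), stringsAsFactors = FALSE)))
}

#' Plot integrated score profiles of a fitted prioritization
#'
#' Draws, per disease, the sorted integrated scores on a log-rank axis and
#' marks where the known seeds fall -- a quick visual of how concentrated
#' the disease signal is.
#'
#' @param x A `"lncprop"` fit.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.lncprop <- function(x, ...) {
  D <- nrow(x$integrated)
  cols <- grDevices::hcl.colors(max(3L, D), "Dark 3")
  ymax <- max(x$integrated)
  graphics::plot(c(1, ncol(x$integrated)), c(0, ymax), type = "n",
                 log = "x", xlab = "rank", ylab = "integrated score", ...)
  for (i in seq_len(D)) {
    d <- rownames(x$integrated)[i]
    r <- rank_candidates(x$integrated[d, ])
    graphics::lines(r$rank, r$score, col = cols[i], lwd = 1.5)
    sr <- r$rank[r$lncrna %in% (x$seeds[[d]] %||% character(0L))]
    graphics::points(sr, r$score[sr], col = cols[i], pch = 16, cex = 0.7)
  }
  graphics::legend("topright", legend = rownames(x$integrated),
                   col = cols[seq_len(D)], lwd = 1.5, bty = "n", cex = 0.8)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
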