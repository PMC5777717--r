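# Per-disease inference of the lncRNA-lncRNA competing network.
#
# Stage 1: significant miRNA-lncRNA co-expression (Pearson, BH-FDR) within
# the validated interaction prior. Stage 2: for every lncRNA pair sharing at
# least one significant miRNA partner, a hypergeometric test of the overlap
# of their partner sets; BH across all tested pairs; surviving edges weighted
# -log10(p).

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH: `q_(i) = min_{j >= i}(p_(j) * m / j)` clipped to 1, returned
#' in the input order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0L))
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

#' Upper-tail hypergeometric p-value for a shared-partner overlap
#'
#' Two lncRNAs with `K` and `M` significant miRNA partners out of a universe
#' of `N` miRNAs share `x` partners. Under the null the overlap is
#' hypergeometric; the enrichment p-value is `P(X >= x)` (default) or
#' `P(X > x)` with `tail = "gt"`. Computed through the survival function
#' ([stats::phyper()]), never by naive factorials, so large universes are
#' numerically safe.
#'
#' @param x Observed shared-partner count, `0 <= x <= min(K, M)`.
#' @param K,M Partner-set sizes of the two lncRNAs (`K, M <= N`).
#' @param N Universe size (number of miRNAs eligible as partners).
#' @param tail `"geq"` for `P(X >= x)` (default) or `"gt"` for `P(X > x)`.
#' @return p-value in `[0, 1]`. Vectorized over all arguments.
#' @examples
#' hypergeom_edge_pvalue(3, 3, 3, 6)  # 1/20
#' @export
hypergeom_edge_pvalue <- function(x, K, M, N, tail = c("geq", "gt")) {
  tail <- match.arg(tail)
  n <- max(length(x), length(K), length(M), length(N))
  x <- rep_len(as.numeric(x), n); K <- rep_len(as.numeric(K), n)
  M <- rep_len(as.numeric(M), n); N <- rep_len(as.numeric(N), n)
  if (any(x < 0) || any(x > pmin(K, M)))
    stop("'x' must satisfy 0 <= x <= min(K, M)", call. = FALSE)
  if (any(K > N) || any(M > N) || any(K < 0) || any(M < 0))
    stop("'K' and 'M' must satisfy 0 <= K, M <= N", call. = FALSE)
  shift <- if (tail == "geq") 1 else 0
  p <- stats::phyper(x - shift, K, N - K, M, lower.tail = FALSE)
  pmin(pmax(p, 0), 1)
}

#' Pearson co-expression of candidate miRNA-lncRNA pairs
#'
#' Tests exactly the candidate pairs of the validated interaction set whose
#' both members are present in the expression matrices (intersection-first:
#' the BH family is the set of testable validated pairs). `r` is the Pearson
#' product-moment correlation over the shared samples; the two-sided p-value
#' uses the t-transform with `n - 2` degrees of freedom; `q` is BH over the
#' whole tested family. Zero-variance features are skipped with a warning and
#' excluded from the BH family.
#'
#' @param mirna_expr,lncrna_expr Expression matrices with identical ordered
#'   sample columns (see [expression_matrix()]).
#' @param candidates An [interaction_set()] of validated (miRNA, lncRNA)
#'   pairs.
#' @return A data frame with columns `mirna`, `lncrna`, `r`, `p`, `q`, one
#'   row per testable candidate pair.
#' @export
correlate_pairs <- function(mirna_expr, lncrna_expr, candidates) {
  if (!identical(colnames(mirna_expr), colnames(lncrna_expr)))
    stop("miRNA and lncRNA matrices must share the identical ordered sample set",
         call. = FALSE)
  n <- ncol(mirna_expr)
  if (n < 3L)
    stop("at least 3 shared samples are required for a Pearson p-value",
         call. = FALSE)
  keep <- candidates$mirna %in% rownames(mirna_expr) &
    candidates$lncrna %in% rownames(lncrna_expr)
  mir <- candidates$mirna[keep]
  lnc <- candidates$lncrna[keep]
  if (length(mir) == 0L) {
    warning("no candidate pair is testable in these matrices", call. = FALSE)
    return(data.frame(mirna = character(0L), lncrna = character(0L),
                      r = numeric(0L), p = numeric(0L), q = numeric(0L),
                      stringsAsFactors = FALSE))
  }
  zs_m <- row_standardize(mirna_expr)
  zs_l <- row_standardize(lncrna_expr)
  degen <- mir %in% rownames(mirna_expr)[attr(zs_m, "zero_var")] |
    lnc %in% rownames(lncrna_expr)[attr(zs_l, "zero_var")]
  if (any(degen)) {
    warning(sprintf("skipped %d pair(s) with a zero-variance feature",
                    sum(degen)), call. = FALSE)
    mir <- mir[!degen]; lnc <- lnc[!degen]
  }
  r <- rowSums(zs_m[mir, , drop = FALSE] * zs_l[lnc, , drop = FALSE]) / (n - 1)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  data.frame(mirna = mir, lncrna = lnc, r = unname(r), p = unname(p),
             q = bh_adjust(p), stringsAsFactors = FALSE)
}

# Center/scale rows to unit variance; flags zero-variance rows.
row_standardize <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- rowSums(xc^2)
  zero <- ss <= 0
  ss[zero] <- 1
  out <- xc / sqrt(ss / (ncol(x) - 1))
  attr(out, "zero_var") <- zero
  out
}

#' Collect each lncRNA's significant validated miRNA partners
#'
#' Keeps correlation records with `q <= fdr_coexpr` that pass the sign filter
#' and groups the surviving miRNAs by lncRNA.
#'
#' @param records Data frame from [correlate_pairs()].
#' @param fdr_coexpr BH threshold (default 0.05).
#' @param corr_sign `"both"` (default), `"positive"` or `"negative"`.
#' @return Named list: lncRNA id -> character vector of partner miRNA ids.
#' @export
build_partner_map <- function(records, fdr_coexpr = 0.05,
                              corr_sign = c("both", "positive", "negative")) {
  corr_sign <- match.arg(corr_sign)
  keep <- records$q <= fdr_coexpr
  keep <- keep & switch(corr_sign,
                        both = TRUE,
                        positive = records$r > 0,
                        negative = records$r < 0)
  if (!any(keep)) {
    warning("no significant co-expressed pair survives the filter",
            call. = FALSE)
    return(structure(list(), names = character(0L)))
  }
  rec <- records[keep, , drop = FALSE]
  lapply(split(rec$mirna, factor(rec$lncrna, levels = unique(rec$lncrna))),
         unique)
}

#' Construct a competing-network object
#'
#' @param disease_id Disease label.
#' @param edges Data frame with columns `lncrna_a`, `lncrna_b`, `x`, `p`,
#'   `q`, `weight` (unordered pairs stored once, `lncrna_a < lncrna_b`).
#' @param dropped Optional character vector of lncRNAs that had significant
#'   partners but no surviving edge.
#' @return An object of class `"competing_network"` with elements
#'   `disease_id`, `nodes`, `edges`, `dropped`.
#' @export
competing_network <- function(disease_id, edges, dropped = character(0L)) {
  stopifnot(is.data.frame(edges),
            all(c("lncrna_a", "lncrna_b", "x", "p", "q", "weight") %in%
                  names(edges)))
  if (nrow(edges) > 0L) {
    if (any(edges$lncrna_a == edges$lncrna_b))
      stop("self-loops are not allowed", call. = FALSE)
    if (any(edges$lncrna_a > edges$lncrna_b))
      stop("edge pairs must be stored in lexicographic order", call. = FALSE)
    if (anyDuplicated(paste(edges$lncrna_a, edges$lncrna_b, sep = "\r")))
      stop("duplicate edges", call. = FALSE)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("edge weights must be finite and positive", call. = FALSE)
  }
  nodes <- sort(unique(c(edges$lncrna_a, edges$lncrna_b)))
  structure(list(disease_id = disease_id, nodes = nodes, edges = edges,
                 dropped = dropped),
            class = "competing_network")
}

#' @export
print.competing_network <- function(x, ...) {
  cat(sprintf("Competing lncRNA network '%s': %d nodes, %d edges\n",
              x$disease_id, length(x$nodes), nrow(x$edges)))
  if (length(x$dropped) > 0L)
    cat(sprintf("  (%d lncRNA(s) with significant partners but no surviving edge)\n",
                length(x$dropped)))
  invisible(x)
}

#' Build the disease-specific lncRNA competing network
#'
#' Every unordered lncRNA pair sharing at least one significant miRNA partner
#' (`x >= 1`) is tested with the hypergeometric overlap test; pairs sharing
#' no partner have p = 1 trivially and are never tested, which keeps the BH
#' family meaningful. The universe `N` defaults to the number of distinct
#' miRNAs in the partner map (`universe_mode = "observed_mirnas"`). Pairs
#' with a saturated partner set (`K = N` or `M = N`) are degenerate
#' (p = 1 for any overlap) and are reported as untestable rather than
#' entering the BH family. Edges with `q <= fdr_edge` are kept and weighted
#' `-log10(p)`; nodes with no surviving edge are dropped (they are
#' unreachable by propagation) and reported in `$dropped`.
#'
#' @param partners Partner map from [build_partner_map()].
#' @param disease_id Disease label for the network.
#' @param fdr_edge BH threshold on edge q-values (default 0.05).
#' @param universe_mode `"observed_mirnas"` (default) or `"fixed_value"`.
#' @param fixed_N Universe size when `universe_mode = "fixed_value"`.
#' @param tail Hypergeometric tail convention (see
#'   [hypergeom_edge_pvalue()]).
#' @return A `competing_network` object; `attr(, "untestable")` holds any
#'   saturated pairs.
#' @export
build_network <- function(partners, disease_id = "disease",
                          fdr_edge = 0.05,
                          universe_mode = c("observed_mirnas", "fixed_value"),
                          fixed_N = NULL, tail = c("geq", "gt")) {
  universe_mode <- match.arg(universe_mode)
  tail <- match.arg(tail)
  empty <- data.frame(lncrna_a = character(0L), lncrna_b = character(0L),
                      x = integer(0L), p = numeric(0L), q = numeric(0L),
                      weight = numeric(0L), stringsAsFactors = FALSE)
  if (length(partners) < 2L)
    return(competing_network(disease_id, empty))
  if (universe_mode == "fixed_value") {
    if (is.null(fixed_N))
      stop("universe_mode = 'fixed_value' requires 'fixed_N'", call. = FALSE)
    N <- as.integer(fixed_N)
  } else {
    N <- length(unique(unlist(partners, use.names = FALSE)))
  }
  ids <- sort(names(partners))
  # Candidate pairs with x >= 1: enumerate via shared-miRNA incidence.
  mirnas <- sort(unique(unlist(partners, use.names = FALSE)))
  inc <- matrix(FALSE, nrow = length(ids), ncol = length(mirnas),
                dimnames = list(ids, mirnas))
  for (l in ids) inc[l, partners[[l]]] <- TRUE
  storage.mode(inc) <- "integer"
  shared <- tcrossprod(inc)          # x for every ordered pair
  K <- rowSums(inc)
  iu <- which(upper.tri(shared) & shared >= 1L, arr.ind = TRUE)
  if (nrow(iu) == 0L)
    return(competing_network(disease_id, empty))
  a <- ids[iu[, 1L]]; b <- ids[iu[, 2L]]
  x <- shared[iu]
  Ka <- K[iu[, 1L]]; Kb <- K[iu[, 2L]]
  if (any(Ka > N) || any(Kb > N))
    stop("partner-set size exceeds the universe; increase 'fixed_N'",
         call. = FALSE)
  saturated <- Ka == N | Kb == N
  untestable <- data.frame(lncrna_a = a[saturated], lncrna_b = b[saturated],
                           x = as.integer(x[saturated]),
                           stringsAsFactors = FALSE)
  if (any(saturated)) {
    message(sprintf("%d pair(s) untestable: partner set saturates the %d-miRNA universe",
                    sum(saturated), N))
    a <- a[!saturated]; b <- b[!saturated]; x <- x[!saturated]
    Ka <- Ka[!saturated]; Kb <- Kb[!saturated]
  }
  if (length(a) == 0L) {
    net <- competing_network(disease_id, empty)
    attr(net, "untestable") <- untestable
    return(net)
  }
  p <- hypergeom_edge_pvalue(x, Ka, Kb, N, tail = tail)
  q <- bh_adjust(p)
  keep <- q <= fdr_edge
  p_floor <- .Machine$double.xmin
  if (any(p[keep] < p_floor)) {
    message("p-value underflow: edge weight capped at -log10(double.xmin)")
  }
  weight <- -log10(pmax(p, p_floor))
  edges <- data.frame(lncrna_a = a[keep], lncrna_b = b[keep],
                      x = as.integer(x[keep]), p = p[keep], q = q[keep],
                      weight = weight[keep], stringsAsFactors = FALSE)
  ord <- order(edges$lncrna_a, edges$lncrna_b)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  dropped <- setdiff(ids, unique(c(edges$lncrna_a, edges$lncrna_b)))
  net <- competing_network(disease_id, edges, dropped = dropped)
  attr(net, "untestable") <- untestable
  net
}

#' Infer a disease's competing network from expression data
#'
#' Convenience wrapper running [correlate_pairs()], [build_partner_map()] and
#' [build_network()] with a single control object.
#'
#' @param mirna_expr,lncrna_expr Paired expression matrices for one disease.
#' @param candidates Validated interaction set.
#' @param disease_id Disease label.
#' @param control A [lncprop_control()] object (or list of overrides).
#' @return A `competing_network`.
#' @export
infer_network <- function(mirna_expr, lncrna_expr, candidates,
                          disease_id = "disease", control = lncprop_control()) {
  control <- as_control(control)
  rec <- correlate_pairs(mirna_expr, lncrna_expr, candidates)
  partners <- suppressWarnings(
    build_partner_map(rec, fdr_coexpr = control$fdr_coexpr,
                      corr_sign = control$corr_sign))
  net <- build_network(partners, disease_id = disease_id,
                       fdr_edge = control$fdr_edge,
                       universe_mode = control$universe_mode,
                       fixed_N = control$fixed_N, tail = control$tail)
  attr(net, "n_pairs_tested") <- nrow(rec)
  attr(net, "n_pairs_significant") <- length(unlist(partners, use.names = FALSE))
  net
}
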