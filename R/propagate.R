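# Random walk with restart over a competing network. Pure linear algebra:
# no randomness anywhere in propagation.

# Weighted adjacency of a competing network as a dense matrix.
adjacency_matrix <- function(network) {
  nodes <- network$nodes
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- network$edges
  if (nrow(e) > 0L) {
    ia <- match(e$lncrna_a, nodes)
    ib <- match(e$lncrna_b, nodes)
    W[cbind(ia, ib)] <- e$weight
    W[cbind(ib, ia)] <- e$weight
  }
  W
}

# Normalized transition matrix. Column normalization gives the random-walk
# convention W[u,v] = w(u,v) / sum_z w(z,v); symmetric gives
# D^{-1/2} A D^{-1/2}.
transition_matrix <- function(network, norm = c("column", "symmetric")) {
  norm <- match.arg(norm)
  A <- adjacency_matrix(network)
  deg <- colSums(A)
  deg[deg == 0] <- 1  # isolated nodes cannot occur (nodes = edge endpoints)
  if (norm == "column") {
    sweep(A, 2L, deg, "/")
  } else {
    d <- 1 / sqrt(deg)
    A * outer(d, d)
  }
}

#' Random walk with restart from seed lncRNAs
#'
#' Iterates `s <- (1 - r) W s + r e` where `W` is the normalized weighted
#' adjacency and `e` the restart vector, uniform over the seeds present in
#' the network and summing to 1. Iteration stops when the L1 change drops to
#' `tol` or after `max_iter` steps (flagged if not converged). With the
#' default column normalization the fixed point is a probability vector
#' (sums to 1); with symmetric normalization the fixed point is rescaled to
#' sum to 1 so scores remain comparable.
#'
#' Seeds absent from the network are dropped with a named warning. If no
#' seed overlaps the network the disease is unseedable: the all-zero vector
#' is returned with `attr(, "unseeded") = TRUE`, and any signal for that
#' disease must come from phenotype integration across other diseases.
#'
#' @param network A `competing_network`.
#' @param seeds Character vector of seed lncRNA ids.
#' @param restart_prob Restart probability `r` in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter Maximum iterations.
#' @param norm `"column"` (default) or `"symmetric"` normalization.
#' @param method `"iterative"` (default) power iteration, or `"direct"`
#'   dense solve of `(I - (1-r) W) s = r e` (identical fixed point; used
#'   mainly for cross-checking).
#' @return Named numeric vector of scores over `network$nodes`, with
#'   attributes `iterations`, `converged`, `unseeded`.
#' @examples
#' net <- competing_network("d", data.frame(
#'   lncrna_a = "A", lncrna_b = "B", x = 1L, p = 0.01, q = 0.01, weight = 2))
#' rwr(net, "A", restart_prob = 0.5)  # (2/3, 1/3)
#' @export
rwr <- function(network, seeds, restart_prob = 0.7, tol = 1e-8,
                max_iter = 1000L, norm = c("column", "symmetric"),
                method = c("iterative", "direct")) {
  norm <- match.arg(norm)
  method <- match.arg(method)
  if (restart_prob <= 0 || restart_prob > 1)
    stop("'restart_prob' must lie in (0, 1]", call. = FALSE)
  nodes <- network$nodes
  if (length(nodes) == 0L)
    stop("network is empty", call. = FALSE)
  missing <- setdiff(seeds, nodes)
  if (length(missing) > 0L)
    warning(sprintf("seed(s) absent from network '%s': %s",
                    network$disease_id, paste(missing, collapse = ", ")),
            call. = FALSE)
  seeds <- intersect(seeds, nodes)
  s <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(seeds) == 0L) {
    attr(s, "iterations") <- 0L
    attr(s, "converged") <- TRUE
    attr(s, "unseeded") <- TRUE
    return(s)
  }
  e <- stats::setNames(numeric(length(nodes)), nodes)
  e[seeds] <- 1 / length(seeds)
  r <- restart_prob
  if (r == 1) {
    s <- e
    attr(s, "iterations") <- 0L
    attr(s, "converged") <- TRUE
    attr(s, "unseeded") <- FALSE
    return(s)
  }
  W <- transition_matrix(network, norm = norm)
  if (method == "direct") {
    A <- diag(length(nodes)) - (1 - r) * W
    s[] <- solve(A, r * e)
    iters <- 0L
    converged <- TRUE
  } else {
    s <- e
    converged <- FALSE
    iters <- 0L
    for (it in seq_len(max_iter)) {
      s_new <- (1 - r) * as.vector(W %*% s) + r * e
      delta <- sum(abs(s_new - s))
      s[] <- s_new
      iters <- it
      if (delta <= tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning(sprintf("random walk did not converge within %d iterations (L1 change %.3g)",
                      max_iter, delta), call. = FALSE)
  }
  if (norm == "symmetric") {
    tot <- sum(s)
    if (tot > 0) s <- s / tot
  }
  attr(s, "iterations") <- iters
  attr(s, "converged") <- converged
  attr(s, "unseeded") <- FALSE
  s
}

#' Per-disease propagation score table
#'
#' Runs [rwr()] for every disease and arranges the scores in a
#' disease-by-lncRNA matrix over the global candidate universe (the union of
#' all network node sets). An lncRNA absent from a disease's network
#' implicitly scores 0 for that disease.
#'
#' @param networks Named list of `competing_network` objects (names = disease
#'   ids).
#' @param seedsets Named list of seed vectors; every disease with seeds must
#'   have a network.
#' @param control A [lncprop_control()] object.
#' @return Numeric matrix (diseases x lncRNAs) with attribute `unseeded`, a
#'   logical vector flagging diseases whose seeds missed the network.
#' @export
score_table <- function(networks, seedsets, control = lncprop_control()) {
  control <- as_control(control)
  diseases <- names(networks)
  if (is.null(diseases) || any(!nzchar(diseases)))
    stop("'networks' must be a named list keyed by disease id", call. = FALSE)
  orphan <- setdiff(names(seedsets), diseases)
  if (length(orphan) > 0L)
    stop("disease(s) with seeds but no network: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  universe <- sort(unique(unlist(lapply(networks, `[[`, "nodes"),
                                 use.names = FALSE)))
  S <- matrix(0, nrow = length(diseases), ncol = length(universe),
              dimnames = list(diseases, universe))
  unseeded <- stats::setNames(logical(length(diseases)), diseases)
  for (d in diseases) {
    sv <- rwr(networks[[d]],
              if (is.null(seedsets[[d]])) character(0L) else seedsets[[d]],
              restart_prob = control$restart_prob, tol = control$rwr_tol,
              max_iter = control$rwr_max_iter, norm = control$norm)
    S[d, names(sv)] <- sv
    unseeded[d] <- isTRUE(attr(sv, "unseeded"))
  }
  attr(S, "unseeded") <- unseeded
  S
}
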