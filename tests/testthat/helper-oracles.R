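# Independent oracles used across the suite. Each reimplements the checked
# quantity from first principles, never through the package's own code path.

# Exact hypergeometric upper tail by combinatorial enumeration:
# P(X >= x) = sum_{t=x}^{min(K,M)} C(K,t) C(N-K,M-t) / C(N,M).
# For N <= 25 every product of binomials is an exact integer below 2^53,
# so base choose() is exact and the only rounding is the final division.
oracle_hyper_tail <- function(x, K, M, N) {
  ts <- seq.int(x, min(K, M))
  if (length(ts) == 0L || x > min(K, M)) return(0)
  sum(choose(K, ts) * choose(N - K, M - ts)) / choose(N, M)
}

# Direct dense linear-system solution of the restart walk:
# (I - (1-r) W) s = r e, W column-normalized from the raw edge list.
oracle_rwr_solve <- function(edges, nodes, seeds, r) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$lncrna_a[i]; b <- edges$lncrna_b[i]; w <- edges$weight[i]
    A[a, b] <- A[a, b] + w
    A[b, a] <- A[b, a] + w
  }
  cs <- colSums(A)
  cs[cs == 0] <- 1
  W <- sweep(A, 2L, cs, "/")
  e <- stats::setNames(numeric(n), nodes)
  e[seeds] <- 1 / length(seeds)
  drop(solve(diag(n) - (1 - r) * W, r * e))
}

# Mann-Whitney AUC by explicit pair counting over scores.
oracle_auc_pairs <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores)
    wins <- wins + sum(p > neg_scores) + 0.5 * sum(p == neg_scores)
  wins / (length(pos_scores) * length(neg_scores))
}

# Step-up Benjamini-Hochberg from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Small undirected random graph as a competing_network, guaranteed
# connected through a spanning path so propagation reaches everything.
random_test_network <- function(n_nodes, extra_edges, disease = "toy") {
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  a <- nodes[-n_nodes]; b <- nodes[-1L]
  if (extra_edges > 0L) {
    i <- sample.int(n_nodes, extra_edges, replace = TRUE)
    j <- sample.int(n_nodes, extra_edges, replace = TRUE)
    keep <- i != j
    a <- c(a, nodes[pmin(i, j)[keep]])
    b <- c(b, nodes[pmax(i, j)[keep]])
  }
  key <- paste(a, b)
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]
  p <- runif(length(a), 1e-8, 0.04)
  edges <- data.frame(lncrna_a = a, lncrna_b = b, x = 1L, p = p, q = p,
                      weight = -log10(p), stringsAsFactors = FALSE)
  competing_network(disease, edges)
}

# A small two-disease corpus of prebuilt networks for evaluation tests.
toy_eval_corpus <- function() {
  edges1 <- data.frame(
    lncrna_a = c("A", "A", "B", "C"), lncrna_b = c("B", "C", "C", "D"),
    x = 1L, p = 0.001, q = 0.001, weight = 3, stringsAsFactors = FALSE)
  edges2 <- data.frame(
    lncrna_a = c("C", "D", "E"), lncrna_b = c("D", "E", "F"),
    x = 1L, p = 0.001, q = 0.001, weight = 3, stringsAsFactors = FALSE)
  networks <- list(d1 = competing_network("d1", edges1),
                   d2 = competing_network("d2", edges2))
  seeds <- list(d1 = c("A", "B"), d2 = c("E", "F"))
  P <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("d1", "d2"), c("d1", "d2")))
  list(networks = networks, seeds = seeds, P = P)
}
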