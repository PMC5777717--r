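# Co-expression, hypergeometric edge test, BH correction, network build.

make_expr <- function(rows, samples = paste0("s", seq_len(ncol_)), ncol_) {
  m <- do.call(rbind, rows)
  expression_matrix(m, names(rows), samples)
}

test_that("correlate_pairs recovers exact and hand-computed correlations", {
  mir <- expression_matrix(rbind(m1 = 1:10, m2 = c(4, 3, 2, 1, 5, 6, 7, 8, 9, 10)),
                           c("m1", "m2"), paste0("s", 1:10))
  lnc <- expression_matrix(rbind(l1 = 2 * (1:10) + 1, l2 = 10:1),
                           c("l1", "l2"), paste0("s", 1:10))
  cand <- interaction_set(c("m1", "m1"), c("l1", "l2"))
  rec <- correlate_pairs(mir, lnc, cand)
  expect_equal(rec$r[rec$lncrna == "l1"], 1)            # exact linear
  expect_equal(rec$r[rec$lncrna == "l2"], -1)           # exact anti
  expect_equal(rec$p[rec$lncrna == "l1"], 0)

  # n = 5 hand case against the independent cor.test route
  mir5 <- expression_matrix(rbind(m = c(1, 2, 3, 4, 5)), "m", paste0("s", 1:5))
  lnc5 <- expression_matrix(rbind(l = c(2, 1, 4, 3, 5)), "l", paste0("s", 1:5))
  rec5 <- correlate_pairs(mir5, lnc5, interaction_set("m", "l"))
  ct <- cor.test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(rec5$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(rec5$p, ct$p.value, tolerance = 1e-12)
})

test_that("correlate_pairs guards sample alignment, size and variance", {
  mir <- expression_matrix(rbind(m = 1:4), "m", paste0("s", 1:4))
  lnc_wrong <- expression_matrix(rbind(l = 1:4), "l", paste0("x", 1:4))
  cand <- interaction_set("m", "l")
  expect_error(correlate_pairs(mir, lnc_wrong, cand), "sample")

  mir2 <- expression_matrix(rbind(m = 1:2), "m", paste0("s", 1:2))
  lnc2 <- expression_matrix(rbind(l = 1:2), "l", paste0("s", 1:2))
  expect_error(correlate_pairs(mir2, lnc2, cand), "3 shared samples")

  lnc_flat <- expression_matrix(rbind(l = rep(1, 4), l2 = c(1, 3, 2, 4)),
                                c("l", "l2"), paste0("s", 1:4))
  cand2 <- interaction_set(c("m", "m"), c("l", "l2"))
  expect_warning(rec <- correlate_pairs(mir, lnc_flat, cand2),
                 "zero-variance")
  expect_identical(rec$lncrna, "l2")  # flat feature out of the BH family
})

test_that("partner map applies FDR threshold and sign filter", {
  rec <- data.frame(mirna = c("m1", "m2", "m3"), lncrna = c("l1", "l1", "l2"),
                    r = c(-0.5, 0.6, 0.9), p = c(0.001, 0.01, 0.2),
                    q = c(0.01, 0.04, 0.2), stringsAsFactors = FALSE)
  pm <- build_partner_map(rec, fdr_coexpr = 0.05)
  expect_named(pm, "l1")
  expect_setequal(pm$l1, c("m1", "m2"))

  pm_neg <- build_partner_map(rec, corr_sign = "negative")
  expect_identical(unname(unlist(pm_neg)), "m1")

  expect_warning(empty <- build_partner_map(rec, fdr_coexpr = 1e-6),
                 "no significant")
  expect_length(empty, 0L)
})

test_that("hypergeometric edge p-value matches exact enumeration", {
  expect_equal(hypergeom_edge_pvalue(0, 3, 4, 10), 1)   # P(X >= 0) = 1
  expect_equal(hypergeom_edge_pvalue(3, 3, 3, 6), 1 / 20)
  # N=10, K=4, M=5, x=3: sum_{t=3}^{4} C(4,t) C(6,5-t) / C(10,5)
  expect_equal(hypergeom_edge_pvalue(3, 4, 5, 10),
               (choose(4, 3) * choose(6, 2) + choose(4, 4) * choose(6, 1)) /
                 choose(10, 5), tolerance = 1e-14)
  # the paper's literal printed bound excludes the observed overlap
  expect_equal(hypergeom_edge_pvalue(3, 4, 5, 10, tail = "gt"),
               choose(4, 4) * choose(6, 1) / choose(10, 5),
               tolerance = 1e-14)
  expect_error(hypergeom_edge_pvalue(4, 3, 5, 10), "min\\(K, M\\)")
  expect_error(hypergeom_edge_pvalue(1, 11, 5, 10), "<= N")
})

test_that("edge p-value is monotone non-increasing in the overlap", {
  for (N in c(8L, 15L, 24L)) {
    K <- sample(N, 1); M <- sample(N, 1)
    p <- hypergeom_edge_pvalue(0:min(K, M), K, M, N)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("bh_adjust equals the step-up definition and p.adjust edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
})

test_that("network build gates on x >= 1, applies BH, and weights edges", {
  # 4 tested pairs with designed raw p; BH step-up keeps 3 at 0.05
  partners <- list(a = c("m1", "m2"), b = c("m1", "m2"), c = "m1",
                   d = c("m3"), e = c("m3"))
  net <- build_network(partners, "toy", fdr_edge = 1)  # keep all, inspect
  # pairs sharing no miRNA (e.g. a-d) must never be tested
  keys <- paste(net$edges$lncrna_a, net$edges$lncrna_b)
  expect_false(any(grepl("^a d$|^a e$|^b d$|^b e$|^c d$|^c e$", keys)))
  expect_true(all(net$edges$x >= 1L))
  expect_equal(net$edges$weight, -log10(net$edges$p))
  # q consistent with an independent BH pass
  expect_equal(net$edges$q, oracle_bh(net$edges$p), tolerance = 1e-12)
})

test_that("BH retention on the hand-computed 4-pair example", {
  q <- bh_adjust(c(0.001, 0.01, 0.02, 0.5))
  expect_equal(q, c(0.004, 0.02, 0.8 / 30, 0.5), tolerance = 1e-12)
  expect_identical(sum(q <= 0.05), 3L)
})

test_that("saturated partner sets are untestable, not significant", {
  # every lncRNA saturates the 5-miRNA universe: degenerate test
  partners <- list(a = paste0("m", 1:5), b = paste0("m", 1:5),
                   c = paste0("m", 1:5))
  expect_message(net <- build_network(partners, "sat"), "untestable")
  expect_identical(nrow(net$edges), 0L)
  expect_identical(nrow(attr(net, "untestable")), 3L)
})

test_that("fixed universe mode is honored and validated", {
  partners <- list(a = c("m1", "m2", "m3"), b = c("m1", "m2", "m3"))
  net <- build_network(partners, universe_mode = "fixed_value", fixed_N = 7,
                       fdr_edge = 1)
  expect_equal(net$edges$p, oracle_hyper_tail(3, 3, 3, 7), tolerance = 1e-12)
  expect_error(build_network(partners, universe_mode = "fixed_value"),
               "fixed_N")
  expect_error(build_network(partners, universe_mode = "fixed_value",
                             fixed_N = 2), "universe")
})

test_that("network construction is deterministic byte-for-byte", {
  fx <- worked_fixture()
  n1 <- suppressMessages(infer_network(fx$mirna$D1, fx$lncrna$D1,
                                       fx$interactions, "D1"))
  n2 <- suppressMessages(infer_network(fx$mirna$D1, fx$lncrna$D1,
                                       fx$interactions, "D1"))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_network(n1, p1); write_network(n2, p2)
  expect_identical(readLines(p1), readLines(p2))
})
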