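# Random walk with restart: closed forms, linear-solve equivalence,
# conservation, locality.

two_node_net <- function(w = 2) {
  competing_network("two", data.frame(
    lncrna_a = "A", lncrna_b = "B", x = 1L, p = 10^-w, q = 10^-w,
    weight = w, stringsAsFactors = FALSE))
}

path_net <- function(n = 5L) {
  nodes <- LETTERS[seq_len(n)]
  competing_network("path", data.frame(
    lncrna_a = nodes[-n], lncrna_b = nodes[-1L], x = 1L, p = 0.001,
    q = 0.001, weight = 3, stringsAsFactors = FALSE))
}

test_that("restart-only limit returns the seed vector exactly", {
  s <- rwr(path_net(), c("A", "C"), restart_prob = 1)
  expect_equal(unname(s[c("A", "C")]), c(0.5, 0.5))
  expect_equal(sum(s), 1)
  expect_identical(attr(s, "iterations"), 0L)
})

test_that("two-node closed form: r = 0.5, seed A gives (2/3, 1/3)", {
  s <- rwr(two_node_net(), "A", restart_prob = 0.5, tol = 1e-12)
  expect_equal(unname(s["A"]), 2 / 3, tolerance = 1e-9)
  expect_equal(unname(s["B"]), 1 / 3, tolerance = 1e-9)
})

test_that("iterative fixed point matches the direct linear solve", {
  net <- path_net(5L)
  s_it <- rwr(net, "A", restart_prob = 0.7, tol = 1e-10)
  s_or <- oracle_rwr_solve(net$edges, net$nodes, "A", 0.7)
  expect_equal(as.numeric(s_it), as.numeric(s_or[names(s_it)]),
               tolerance = 1e-8)
  s_dir <- rwr(net, "A", restart_prob = 0.7, method = "direct")
  expect_equal(as.numeric(s_dir), as.numeric(s_or[names(s_dir)]),
               tolerance = 1e-12)
})

test_that("converged scores conserve mass and satisfy the fixed point", {
  set.seed(3)
  for (i in 1:5) {
    net <- random_test_network(sample(10:60, 1), sample(20:80, 1))
    seeds <- sample(net$nodes, 3)
    s <- rwr(net, seeds, restart_prob = 0.7, tol = 1e-10)
    expect_equal(sum(s), 1, tolerance = 1e-9)
    # residual of s = (1-r) W s + r e below tolerance
    or <- oracle_rwr_solve(net$edges, net$nodes, seeds, 0.7)
    expect_equal(as.numeric(s), as.numeric(or[names(s)]), tolerance = 1e-7)
  }
})

test_that("score is non-increasing with hop distance on a path", {
  s <- rwr(path_net(7L), "A", restart_prob = 0.7, tol = 1e-12)
  expect_true(all(diff(s[LETTERS[1:7]]) <= 1e-12))
})

test_that("absent and missing seeds are handled as specified", {
  net <- path_net()
  expect_warning(s <- rwr(net, c("A", "ZZ"), restart_prob = 0.7), "ZZ")
  expect_false(attr(s, "unseeded"))
  s0 <- suppressWarnings(rwr(net, "ZZ", restart_prob = 0.7))
  expect_true(attr(s0, "unseeded"))
  expect_equal(sum(s0), 0)
  expect_error(rwr(net, "A", restart_prob = 1.5), "restart_prob")
})

test_that("symmetric normalization is exposed and renormalized", {
  net <- path_net()
  s <- rwr(net, "A", restart_prob = 0.7, norm = "symmetric")
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_true(which.max(s) == 1L)
})

test_that("score_table spans the union universe with implicit zeros", {
  tc <- toy_eval_corpus()
  S <- score_table(tc$networks, tc$seeds)
  expect_identical(colnames(S), sort(unique(c("A", "B", "C", "D", "E", "F"))))
  expect_equal(S["d1", "F"], 0)   # F absent from d1's network
  expect_equal(rowSums(S), c(d1 = 1, d2 = 1), tolerance = 1e-9)

  # identical inputs give identical rows
  nets2 <- list(x = tc$networks$d1, y = tc$networks$d1)
  S2 <- score_table(nets2, list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(S2["x", ], S2["y", ])

  expect_error(score_table(tc$networks["d1"], tc$seeds), "no network")
})
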