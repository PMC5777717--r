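# AUC machinery and the LOOCV / robustness experiments.

test_that("auc_from_ranks matches pair counting on canonical cases", {
  expect_equal(auc_from_ranks(3, 10), 7 / 9)
  expect_equal(auc_from_ranks(1:3, 10, 3), 1)       # positives on top
  expect_equal(auc_from_ranks((10 + 1) / 2, 10), 0.5)  # everything tied
  expect_error(auc_from_ranks(numeric(0), 5), "at least one")
  expect_error(auc_from_ranks(1:5, 5), "at least one")
  expect_error(auc_from_ranks(7, 5), "n_candidates")
})

test_that("Mann-Whitney, pair counting and ROC trapezoid agree", {
  set.seed(21)
  for (i in 1:50) {
    n_pos <- sample(1:5, 1); n_neg <- sample(3:40, 1)
    # duplicate-heavy scores exercise the tie conventions
    pos <- sample(seq(0, 1, by = 0.1), n_pos, replace = TRUE)
    neg <- sample(seq(0, 1, by = 0.1), n_neg, replace = TRUE)
    a_pairs <- oracle_auc_pairs(pos, neg)
    a_trap <- auc_trapezoid(roc_points(pos, neg))
    all_sc <- c(pos, neg)
    midranks <- rank(-all_sc, ties.method = "average")[seq_len(n_pos)]
    a_mw <- auc_from_ranks(midranks, n_pos + n_neg, n_pos)
    expect_equal(a_trap, a_pairs, tolerance = 1e-12)
    expect_equal(a_mw, a_pairs, tolerance = 1e-12)
  }
})

test_that("loocv ranks a perfectly informative disease at AUC 1", {
  tc <- toy_eval_corpus()
  # d1's seeds A,B sit in a tight clique; give d1 a strongly separated module
  ev <- suppressWarnings(loocv(tc$networks, tc$seeds, tc$P))
  expect_s3_class(ev, "lncprop_eval")
  expect_true(all(ev$auc >= 0 & ev$auc <= 1))
  expect_equal(ev$mean_auc, mean(ev$auc))
  rec <- ev$records
  expect_true(all(rec$rank <= rec$n_candidates))
  expect_true(all(rec$percentile > 0 & rec$percentile <= 1))
  # per-disease ROC integrates back to the per-disease AUC
  for (d in names(ev$roc))
    expect_equal(auc_trapezoid(ev$roc[[d]]), ev$auc[[d]], tolerance = 1e-9)
})

test_that("phenotype ablation equals loocv under an identity matrix", {
  tc <- toy_eval_corpus()
  P_id <- diag(2); dimnames(P_id) <- dimnames(tc$P)
  ev_id <- suppressWarnings(loocv(tc$networks, tc$seeds, P_id))
  ev_ab <- suppressWarnings(ablate_phenotype(tc$networks, tc$seeds))
  expect_equal(ev_id$auc, ev_ab$auc)
  expect_equal(ev_id$records$rank, ev_ab$records$rank)
})

test_that("diseases without enough usable seeds are skipped with warning", {
  tc <- toy_eval_corpus()
  seeds <- list(d1 = c("A", "B"), d2 = "E")
  expect_warning(ev <- loocv(tc$networks, seeds, tc$P), "skipped")
  expect_identical(names(ev$auc), "d1")
  expect_identical(ev$skipped, "d2")
  none <- list(d1 = "A", d2 = "E")
  expect_error(suppressWarnings(loocv(tc$networks, none, tc$P)),
               "no disease")
})

test_that("phenotype permutation needs 3 diseases and is reproducible", {
  tc <- toy_eval_corpus()
  expect_error(permute_phenotype(tc$networks, tc$seeds, tc$P, reps = 3),
               "3 diseases")
  nets3 <- c(tc$networks, list(d3 = tc$networks$d1))
  seeds3 <- c(tc$seeds, list(d3 = c("A", "B")))
  P3 <- matrix(0.2, 3, 3, dimnames = list(names(nets3), names(nets3)))
  diag(P3) <- 1
  P3["d1", "d2"] <- P3["d2", "d1"] <- 0.8
  ctl <- lncprop_control(rng_seed = 77)
  r1 <- suppressWarnings(permute_phenotype(nets3, seeds3, P3, reps = 8,
                                           control = ctl))
  r2 <- suppressWarnings(permute_phenotype(nets3, seeds3, P3, reps = 8,
                                           control = ctl))
  expect_identical(r1$mean_aucs, r2$mean_aucs)
  expect_length(r1$mean_aucs, 8L)
})

test_that("offdiag permutation preserves symmetry, diagonal and values", {
  P <- matrix(c(1, .2, .3, .2, 1, .7, .3, .7, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  set.seed(1)
  Pp <- lncprop:::permute_P(P, "offdiag")
  expect_equal(diag(Pp), diag(P))
  expect_equal(Pp, t(Pp))
  expect_setequal(Pp[upper.tri(Pp)], P[upper.tri(P)])
})

test_that("random seed control validates its pool and reproduces", {
  tc <- toy_eval_corpus()
  expect_error(random_seed_control(tc$networks, tc$seeds, tc$P,
                                   pool = c("A", "C", "D"), reps = 1),
               "disjoint")
  expect_error(random_seed_control(tc$networks, tc$seeds, tc$P,
                                   pool = "C", reps = 1), "smaller")
  ctl <- lncprop_control(rng_seed = 5)
  r1 <- suppressWarnings(random_seed_control(tc$networks, tc$seeds, tc$P,
                                             pool = c("C", "D"), reps = 2,
                                             control = ctl))
  r2 <- suppressWarnings(random_seed_control(tc$networks, tc$seeds, tc$P,
                                             pool = c("C", "D"), reps = 2,
                                             control = ctl))
  expect_identical(r1$mean_aucs, r2$mean_aucs)
})

test_that("subsampling at k = D reproduces the primary loocv mean", {
  tc <- toy_eval_corpus()
  ev <- suppressWarnings(loocv(tc$networks, tc$seeds, tc$P))
  sub <- suppressWarnings(subsample_diseases(tc$networks, tc$seeds, tc$P,
                                             k = 2, reps = 3,
                                             control = lncprop_control(rng_seed = 1)))
  expect_true(all(abs(sub$mean_aucs - ev$mean_auc) < 1e-12))
  expect_error(subsample_diseases(tc$networks, tc$seeds, tc$P, k = 1,
                                  reps = 1), "k")
  expect_error(subsample_diseases(tc$networks, tc$seeds, tc$P, k = 3,
                                  reps = 1), "k")
})

test_that("cross-disease-only with identity phenotype is uninformative", {
  tc <- toy_eval_corpus()
  P_id <- diag(2); dimnames(P_id) <- dimnames(tc$P)
  cd <- cross_disease_only(tc$networks, tc$seeds, P_id)
  expect_equal(unname(cd$auc), c(0.5, 0.5))  # all-zero scores, tie AUC
  expect_error(cross_disease_only(tc$networks["d1"], tc$seeds["d1"], tc$P),
               "2 diseases")
})

test_that("two identical diseases transfer each other's seeds to the top", {
  net <- toy_eval_corpus()$networks$d1
  nets <- list(x = net, y = net)
  seeds <- list(x = c("A", "B"), y = c("A", "B"))
  P <- matrix(c(1, .9, .9, 1), 2, 2, dimnames = list(c("x", "y"),
                                                     c("x", "y")))
  cd <- cross_disease_only(nets, seeds, P)
  expect_true(all(cd$auc == 1))
})

test_that("non_disease_pool excludes every seed", {
  tc <- toy_eval_corpus()
  pool <- non_disease_pool(tc$networks, tc$seeds)
  expect_setequal(pool, c("C", "D"))
})

test_that("phenotype integration outranks its controls across regenerated corpora", {
  # the ordering AUC(true P) > AUC(identity P) and > mean AUC(permuted P)
  # must hold in at least 95% of independently regenerated corpora
  ok_id <- 0L; ok_perm <- 0L; n_seeds <- 20L
  for (sd in seq_len(n_seeds)) {
    corpus <- generate_corpus(synth_spec(rng_seed = 500L + sd))
    fit <- suppressWarnings(lncprop(corpus,
                                    control = lncprop_control(rng_seed = sd)))
    ev <- suppressWarnings(loocv(fit))$mean_auc
    id <- suppressWarnings(ablate_phenotype(fit))$mean_auc
    pm <- suppressWarnings(permute_phenotype(fit, reps = 10L))$mean
    ok_id <- ok_id + (ev > id)
    ok_perm <- ok_perm + (ev > pm)
  }
  expect_gte(ok_id, ceiling(0.95 * n_seeds))
  expect_gte(ok_perm, ceiling(0.95 * n_seeds))
})
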