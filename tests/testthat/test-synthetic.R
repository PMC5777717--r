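# Synthetic corpus generator and the worked fixture.

small_spec <- function(...) {
  synth_spec(n_diseases = 2L, n_lncrna = 80L, n_mirna = 20L, n_samples = 30L,
             module_size = 10L, mirnas_per_module = 4L, seeds_per_disease = 3L,
             bg_module_size = 8L, bg_mirnas_per_module = 4L,
             phenotype_blocks = list(1:2), ...)
}

test_that("spec validation names the offending field", {
  expect_error(synth_spec(module_size = 100, n_lncrna = 200, n_diseases = 5),
               "module_size")
  expect_error(synth_spec(seeds_per_disease = 30), "seeds_per_disease")
  expect_error(synth_spec(corr_strength = 1.2), "corr_strength")
  expect_error(synth_spec(phenotype_blocks = list(1:2), n_diseases = 5),
               "phenotype_blocks")
  expect_error(synth_spec(weak_frac = -0.1), "weak_frac")
})

test_that("generation is byte-reproducible from the seed", {
  c1 <- generate_corpus(small_spec(rng_seed = 123))
  c2 <- generate_corpus(small_spec(rng_seed = 123))
  expect_identical(c1$lncrna, c2$lncrna)
  expect_identical(c1$interactions, c2$interactions)
  expect_identical(c1$seeds, c2$seeds)
  c3 <- generate_corpus(small_spec(rng_seed = 124))
  expect_false(identical(c1$lncrna, c3$lncrna))
})

test_that("phenotype matrix is symmetric with unit diagonal and block structure", {
  spec <- synth_spec(rng_seed = 5)
  corpus <- generate_corpus(spec)
  P <- corpus$phenotype
  expect_equal(P, t(P))
  expect_equal(unname(diag(P)), rep(1, spec$n_diseases))
  expect_equal(P["DIS01", "DIS02"], spec$within_block_sim)  # same block
  expect_equal(P["DIS01", "DIS04"], spec$between_block_sim) # across blocks
})

test_that("truth is internally consistent with the emitted corpus", {
  corpus <- generate_corpus(small_spec(rng_seed = 7))
  for (d in names(corpus$seeds)) {
    expect_true(all(corpus$seeds[[d]] %in% corpus$truth$modules[[d]]))
    expect_identical(corpus$truth$true_disease_lncrnas[[d]],
                     corpus$seeds[[d]])
  }
  planted <- corpus$truth$planted_pairs
  key_all <- paste(corpus$interactions$mirna, corpus$interactions$lncrna)
  expect_true(all(paste(planted$mirna, planted$lncrna) %in% key_all))
  # decoys come on top of the planted pairs
  expect_gte(nrow(corpus$interactions), nrow(planted))
})

test_that("near-noiseless corpus shows the predicted assigned-pair correlation", {
  spec <- small_spec(rng_seed = 31, corr_strength = 0.99, noise_sd = 0.01,
                     weak_frac = 0)
  corpus <- generate_corpus(spec)
  d <- "DIS01"
  planted <- corpus$truth$planted_pairs
  mod <- corpus$truth$modules[[d]]
  pp <- planted[planted$lncrna %in% mod &
                  planted$mirna %in% corpus$truth$mirna_modules[[d]], ]
  rs <- vapply(seq_len(nrow(pp)), function(i)
    cor(corpus$lncrna[[d]][pp$lncrna[i], ], corpus$mirna[[d]][pp$mirna[i], ]),
    numeric(1L))
  # loading arithmetic: assigned pairs r ~ corr / sqrt(corr^2 + noise^2)
  pred <- 0.99 / sqrt(0.99^2 + 0.01^2)
  assigned_r <- vapply(split(rs, pp$lncrna), max, numeric(1L))
  expect_true(all(assigned_r > 0.9))
  expect_equal(mean(assigned_r), pred, tolerance = 0.01)
})

test_that("a null corpus yields no partners beyond the false positive rate", {
  spec <- small_spec(rng_seed = 13, corr_strength = 0)
  corpus <- generate_corpus(spec)
  rec <- correlate_pairs(corpus$mirna$DIS01, corpus$lncrna$DIS01,
                         corpus$interactions)
  expect_lt(mean(rec$q <= 0.05), 0.01)
})

test_that("planted pairs stochastically dominate decoys in correlation", {
  corpus <- generate_corpus(small_spec(rng_seed = 17))
  rec <- correlate_pairs(corpus$mirna$DIS01, corpus$lncrna$DIS01,
                         corpus$interactions)
  key <- paste(rec$mirna, rec$lncrna)
  mod <- corpus$truth$modules$DIS01
  planted_here <- paste(corpus$truth$planted_pairs$mirna,
                        corpus$truth$planted_pairs$lncrna)
  is_planted <- key %in% planted_here & rec$lncrna %in% mod
  is_decoy <- !(key %in% planted_here)
  expect_gt(median(abs(rec$r[is_planted])), median(abs(rec$r[is_decoy])))
})

test_that("corpus round-trips through the on-disk input formats", {
  corpus <- generate_corpus(small_spec(rng_seed = 19))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_equal(read_expression(file.path(dir, "DIS01_lncrna.tsv")),
               corpus$lncrna$DIS01)
  expect_equal(read_interactions(file.path(dir, "interactions.tsv")),
               corpus$interactions)
  expect_equal(read_seeds(file.path(dir, "seeds.tsv")), corpus$seeds)
  expect_equal(read_phenotype_matrix(file.path(dir, "phenotype.tsv")),
               corpus$phenotype)
})

test_that("worked fixture recovers its fully enumerable network", {
  fx <- worked_fixture()
  fit <- suppressWarnings(lncprop(fx))
  for (d in c("D1", "D2")) {
    net <- fit$networks[[d]]
    mod <- fx$truth$modules[[d]]
    # the module clique: all 10 unordered pairs, nothing else
    expect_identical(sort(net$nodes), sort(mod))
    expect_identical(nrow(net$edges), 10L)
    # x = K = M = 3 out of a 7-miRNA universe: exact combinatorial oracle
    expect_equal(net$edges$p, rep(oracle_hyper_tail(3, 3, 3, 7), 10),
                 tolerance = 1e-12)
    expect_equal(net$edges$weight, rep(-log10(1 / 35), 10), tolerance = 1e-12)
  }
  # matches the frozen edge-list assets shipped with the package
  for (d in c("D1", "D2")) {
    asset <- system.file("extdata",
                         sprintf("worked_fixture_%s_network.tsv", d),
                         package = "lncprop")
    skip_if(asset == "", "fixture assets not installed")
    tmp <- withr::local_tempfile()
    write_network(fit$networks[[d]], tmp)
    expect_identical(readLines(tmp), readLines(asset))
  }
})

test_that("fixture integration with identity phenotype equals raw scores", {
  fx <- worked_fixture()
  fit <- suppressWarnings(lncprop(fx))
  P_id <- diag(2); dimnames(P_id) <- dimnames(fx$phenotype)
  expect_equal(integrate_scores(fit$scores, P_id), fit$scores,
               ignore_attr = TRUE)
})

test_that("the shared seed transfers across the fixture diseases", {
  fx <- worked_fixture()
  fit <- suppressWarnings(lncprop(fx))
  # L04 seeds both diseases; holding it out for D1 leaves D2's evidence
  ev <- suppressWarnings(loocv(fit))
  rec <- ev$records
  r_shared <- rec$rank[rec$disease == "D1" & rec$held_out == "L04"]
  expect_lte(r_shared, 2L)
})

test_that("planted pairs dominate decoys across regenerated corpora", {
  for (sd in 1:20) {
    corpus <- generate_corpus(small_spec(rng_seed = 700 + sd))
    rec <- correlate_pairs(corpus$mirna$DIS01, corpus$lncrna$DIS01,
                           corpus$interactions)
    key <- paste(rec$mirna, rec$lncrna)
    planted <- paste(corpus$truth$planted_pairs$mirna,
                     corpus$truth$planted_pairs$lncrna)
    in_module <- key %in% planted & rec$lncrna %in% corpus$truth$modules$DIS01
    expect_gt(median(abs(rec$r[in_module])),
              median(abs(rec$r[!(key %in% planted)])))
  }
})
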