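# Synthetic multi-disease corpus with planted ceRNA structure.
#
# Generative model (single latent factor per module): every co-expression
# module m owns one factor g_m ~ N(0,1) per sample. Module miRNAs load on
# the factor with sqrt(mirna_coupling) (so any two module miRNAs correlate
# at mirna_coupling); each module lncRNA is assigned one module miRNA
# (round-robin) and equals corr_strength * miRNA + noise_sd * eps, so the
# expected assigned-pair correlation is corr_strength /
# sqrt(corr_strength^2 + noise_sd^2). Diseases in the same phenotype block
# share a core fraction of their module lncRNAs; background (non-disease)
# ceRNA modules fill the remaining miRNAs so the network universe contains
# well-connected non-disease candidates.

#' Specification of a synthetic multi-disease corpus
#'
#' @param n_diseases Number of diseases (default 5).
#' @param n_lncrna Total lncRNAs (default 300).
#' @param n_mirna Total miRNAs (default 60).
#' @param n_samples Samples per disease (default 50).
#' @param module_size lncRNAs per disease module (default 20).
#' @param mirnas_per_module miRNAs per disease module (default 8).
#' @param corr_strength Loading of a module lncRNA on its assigned miRNA,
#'   in (0, 1] (default 0.7). 0 is allowed and produces a null corpus.
#' @param noise_sd Independent noise standard deviation (default 1.0).
#' @param seeds_per_disease Known disease lncRNAs emitted per disease
#'   (default 6), drawn from the disease's module. Two thirds (rounded up)
#'   come from a per-block pool of recurring disease lncRNAs shared by the
#'   block, the rest from anywhere in the module -- curated disease-lncRNA
#'   corpora show exactly this heavy recurrence of a few famous lncRNAs
#'   across related cancers.
#' @param phenotype_blocks Partition of `1:n_diseases` into related groups
#'   (list of integer vectors). Default: blocks of three (last block takes
#'   the remainder).
#' @param between_block_sim,within_block_sim Off-diagonal phenotype
#'   similarity between/within blocks (defaults 0.1 / 0.7); diagonal is 1.
#' @param share_frac Fraction of a module's lncRNAs shared by every disease
#'   of the same block (default 0.8).
#' @param mirna_coupling Pairwise correlation of miRNAs within a module
#'   (default 0.85), strong enough that strong module members are detected
#'   as partners of most module miRNAs after FDR control.
#' @param weak_frac Fraction of a module's lncRNAs that are only weakly
#'   active in any given disease (default 0.3), drawn independently per
#'   disease -- ceRNA activity is context-dependent across cancer types.
#'   Weak members usually escape detection in that disease and must be
#'   recovered through phenotype transfer from related diseases.
#' @param weak_loading Loading multiplier of a weak member (default 0.7):
#'   weak members usually stay in the network but attach with fewer,
#'   weaker edges, so their own-disease propagation rank is poor.
#' @param decoy_factor Random decoy interactions per planted interaction
#'   (default 2).
#' @param bg_mirnas_per_module miRNAs per background module (default 4);
#'   background modules are carved out of the miRNAs not used by disease
#'   modules, `bg_module_size` lncRNAs each, until either pool is exhausted.
#' @param bg_module_size lncRNAs per background module (default 14); smaller
#'   than disease modules so the network's non-disease bulk is made of many
#'   moderate co-expression neighborhoods.
#' @param bridges_per_pair Bridge lncRNAs between consecutive modules
#'   (disease + background, arranged in a ring; default 1). A bridge loads
#'   on the first two miRNAs of each flanking module, which links the
#'   modules into one giant connected component -- the degree structure
#'   real ceRNA networks show. 0 produces disconnected module islands.
#' @param rng_seed Integer seed; the corpus is fully reproducible from it.
#' @return A validated list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_diseases = 5L, n_lncrna = 300L, n_mirna = 60L,
                       n_samples = 50L, module_size = 20L,
                       mirnas_per_module = 8L, corr_strength = 0.7,
                       noise_sd = 1.0, seeds_per_disease = 6L,
                       phenotype_blocks = NULL, between_block_sim = 0.1,
                       within_block_sim = 0.7, share_frac = 0.8,
                       mirna_coupling = 0.85, weak_frac = 0.3,
                       weak_loading = 0.7, decoy_factor = 2,
                       bg_mirnas_per_module = 4L, bg_module_size = 14L,
                       bridges_per_pair = 1L, rng_seed = NULL) {
  spec <- list(n_diseases = as.integer(n_diseases),
               n_lncrna = as.integer(n_lncrna),
               n_mirna = as.integer(n_mirna),
               n_samples = as.integer(n_samples),
               module_size = as.integer(module_size),
               mirnas_per_module = as.integer(mirnas_per_module),
               corr_strength = corr_strength, noise_sd = noise_sd,
               seeds_per_disease = as.integer(seeds_per_disease),
               phenotype_blocks = phenotype_blocks,
               between_block_sim = between_block_sim,
               within_block_sim = within_block_sim,
               share_frac = share_frac, mirna_coupling = mirna_coupling,
               weak_frac = weak_frac, weak_loading = weak_loading,
               decoy_factor = decoy_factor,
               bg_mirnas_per_module = as.integer(bg_mirnas_per_module),
               bg_module_size = as.integer(bg_module_size),
               bridges_per_pair = as.integer(bridges_per_pair),
               rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed))
  if (is.null(spec$phenotype_blocks)) {
    idx <- seq_len(spec$n_diseases)
    spec$phenotype_blocks <- unname(split(idx, ceiling(idx / 3)))
  }
  validate_synth_spec(spec)
  structure(spec, class = "synth_spec")
}

validate_synth_spec <- function(s) {
  fail <- function(field, msg)
    stop(sprintf("invalid synthetic spec field '%s': %s", field, msg),
         call. = FALSE)
  if (s$n_diseases < 1L) fail("n_diseases", "must be >= 1")
  if (s$module_size * s$n_diseases > s$n_lncrna)
    fail("module_size", "module_size * n_diseases exceeds n_lncrna")
  if (s$mirnas_per_module * s$n_diseases > s$n_mirna)
    fail("mirnas_per_module", "disease modules need more miRNAs than n_mirna")
  if (s$seeds_per_disease > s$module_size)
    fail("seeds_per_disease", "cannot exceed module_size")
  if (s$n_samples < 4L) fail("n_samples", "must be >= 4")
  if (s$corr_strength < 0 || s$corr_strength > 1)
    fail("corr_strength", "must lie in [0, 1]")
  if (s$noise_sd < 0) fail("noise_sd", "must be >= 0")
  if (s$share_frac < 0 || s$share_frac > 1)
    fail("share_frac", "must lie in [0, 1]")
  if (s$mirna_coupling < 0 || s$mirna_coupling > 1)
    fail("mirna_coupling", "must lie in [0, 1]")
  if (s$weak_frac < 0 || s$weak_frac > 1)
    fail("weak_frac", "must lie in [0, 1]")
  if (s$weak_loading < 0 || s$weak_loading > 1)
    fail("weak_loading", "must lie in [0, 1]")
  for (sim in c("between_block_sim", "within_block_sim"))
    if (s[[sim]] < 0 || s[[sim]] > 1) fail(sim, "must lie in [0, 1]")
  blocks <- unlist(s$phenotype_blocks, use.names = FALSE)
  if (!setequal(blocks, seq_len(s$n_diseases)) ||
      length(blocks) != s$n_diseases)
    fail("phenotype_blocks", "must partition 1:n_diseases")
  if (s$decoy_factor < 0) fail("decoy_factor", "must be >= 0")
  if (s$bridges_per_pair < 0L) fail("bridges_per_pair", "must be >= 0")
  if (s$bg_mirnas_per_module < 2L) fail("bg_mirnas_per_module", "must be >= 2")
  if (s$bg_module_size < 2L) fail("bg_module_size", "must be >= 2")
  invisible(s)
}

# One module's expression rows for one disease: factor, miRNA rows, lncRNA
# rows (assigned round-robin to the module miRNAs). A weak_frac share of
# the lncRNAs participates only weakly in this disease's module.
sim_module_rows <- function(mirnas, lncrnas, n_samples, coupling,
                            corr_strength, noise_sd, weak_frac = 0,
                            weak_loading = 1) {
  g <- stats::rnorm(n_samples)
  mir <- t(vapply(seq_along(mirnas), function(i) {
    sqrt(coupling) * g + sqrt(1 - coupling) * stats::rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(mir) <- mirnas
  assign <- mirnas[(seq_along(lncrnas) - 1L) %% length(mirnas) + 1L]
  weak <- stats::runif(length(lncrnas)) < weak_frac
  lnc <- t(vapply(seq_along(lncrnas), function(i) {
    a <- corr_strength * if (weak[i]) weak_loading else 1
    a * mir[assign[i], ] + noise_sd * stats::rnorm(n_samples)
  }, numeric(n_samples)))
  rownames(lnc) <- lncrnas
  list(g = g, mir = mir, lnc = lnc,
       assign = stats::setNames(assign, lncrnas),
       weak = stats::setNames(weak, lncrnas))
}

#' Generate a synthetic multi-disease corpus
#'
#' Produces everything the pipeline consumes -- per-disease paired
#' expression matrices, a validated interaction list (planted module pairs
#' plus random decoys), per-disease seed sets drawn from the planted
#' modules, a block-structured phenotype similarity matrix -- together with
#' the ground truth needed for recovery tests.
#'
#' @param spec A [synth_spec()] (or list of overrides).
#' @return A list of class `"lncprop_corpus"` with elements `lncrna` and
#'   `mirna` (named lists of expression matrices), `interactions`, `seeds`,
#'   `phenotype`, `truth` (module memberships, miRNA modules, planted pairs,
#'   blocks, per-disease true disease lncRNAs) and `spec`.
#' @export
generate_corpus <- function(spec = synth_spec()) {
  if (!inherits(spec, "synth_spec")) spec <- do.call(synth_spec, spec)
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  diseases <- sprintf("DIS%02d", seq_len(spec$n_diseases))
  lnc_ids <- sprintf("LNC%04d", seq_len(spec$n_lncrna))
  mir_ids <- sprintf("MIR%03d", seq_len(spec$n_mirna))

  # --- carve up identifier pools -----------------------------------------
  core_size <- round(spec$share_frac * spec$module_size)
  lnc_pool <- lnc_ids
  take_lnc <- function(n) {
    out <- lnc_pool[seq_len(n)]
    lnc_pool <<- lnc_pool[-seq_len(n)]
    out
  }
  modules <- stats::setNames(vector("list", spec$n_diseases), diseases)
  for (b in spec$phenotype_blocks) {
    core <- take_lnc(core_size)
    for (di in b) {
      priv <- take_lnc(spec$module_size - core_size)
      modules[[diseases[di]]] <- c(core, priv)
    }
  }
  mir_modules <- stats::setNames(
    split(mir_ids[seq_len(spec$mirnas_per_module * spec$n_diseases)],
          rep(seq_len(spec$n_diseases), each = spec$mirnas_per_module)),
    diseases)
  # background modules out of the leftover miRNAs / lncRNAs
  mir_left <- setdiff(mir_ids, unlist(mir_modules, use.names = FALSE))
  bg_mirs <- list(); bg_lncs <- list()
  while (length(mir_left) >= spec$bg_mirnas_per_module &&
         length(lnc_pool) >= spec$bg_module_size) {
    bg_mirs[[length(bg_mirs) + 1L]] <- mir_left[seq_len(spec$bg_mirnas_per_module)]
    mir_left <- mir_left[-seq_len(spec$bg_mirnas_per_module)]
    bg_lncs[[length(bg_lncs) + 1L]] <- take_lnc(spec$bg_module_size)
  }
  # Module graph wiring. Bridge lncRNAs load on two module factors at once
  # and knit the per-disease networks into one giant component, the degree
  # structure real ceRNA networks show. Background modules form a ring;
  # every disease module bridges to every background module, so that in a
  # disease\'s own network its module is as central as the background bulk
  # (a bridge whose disease flank is inactive in some other disease simply
  # attaches to its background flank there as a weak satellite).
  ring <- c(lapply(diseases, function(d)
    list(owner = d, m = mir_modules[[d]], l = modules[[d]])),
    lapply(seq_along(bg_mirs), function(i)
      list(owner = NA_character_, m = bg_mirs[[i]], l = bg_lncs[[i]])))
  n_ring <- length(ring)
  bg_idx <- which(vapply(ring, function(m) is.na(m$owner), logical(1L)))
  d_idx <- setdiff(seq_len(n_ring), bg_idx)
  bridge_pairs <- NULL
  if (length(bg_idx) >= 2L) {
    bridge_pairs <- if (length(bg_idx) >= 3L)
      cbind(bg_idx, c(bg_idx[-1L], bg_idx[1L]))
    else cbind(bg_idx[1L], bg_idx[2L])
  }
  if (length(d_idx) > 0L && length(bg_idx) > 0L)
    bridge_pairs <- rbind(bridge_pairs,
                          as.matrix(expand.grid(d_idx, bg_idx)))
  if (is.null(bridge_pairs) && n_ring >= 2L)
    bridge_pairs <- cbind(1L, 2L)
  bridges <- list()
  if (!is.null(bridge_pairs) && spec$bridges_per_pair > 0L) {
    for (bp in seq_len(nrow(bridge_pairs))) {
      n_avail <- min(spec$bridges_per_pair, length(lnc_pool))
      if (n_avail == 0L) break
      bridges[[length(bridges) + 1L]] <-
        list(lnc = take_lnc(n_avail),
             i = bridge_pairs[bp, 1L], j = bridge_pairs[bp, 2L])
    }
  }

  # --- expression ---------------------------------------------------------
  lnc_mats <- list(); mir_mats <- list()
  for (d in diseases) {
    samples <- sprintf("%s_S%03d", d, seq_len(spec$n_samples))
    lnc <- matrix(stats::rnorm(spec$n_lncrna * spec$n_samples),
                  nrow = spec$n_lncrna, dimnames = list(lnc_ids, samples))
    mir <- matrix(stats::rnorm(spec$n_mirna * spec$n_samples),
                  nrow = spec$n_mirna, dimnames = list(mir_ids, samples))
    factors <- vector("list", n_ring)
    for (ri in seq_len(n_ring)) {
      mod <- ring[[ri]]
      if (!is.na(mod$owner) && mod$owner != d) next  # inactive here
      rows <- sim_module_rows(mod$m, mod$l, spec$n_samples,
                              spec$mirna_coupling, spec$corr_strength,
                              spec$noise_sd, spec$weak_frac,
                              spec$weak_loading)
      mir[mod$m, ] <- rows$mir
      lnc[mod$l, ] <- rows$lnc
      factors[[ri]] <- rows$g
    }
    for (br in bridges) {
      f1 <- if (is.null(factors[[br$i]])) stats::rnorm(spec$n_samples)
            else factors[[br$i]]
      f2 <- if (is.null(factors[[br$j]])) stats::rnorm(spec$n_samples)
            else factors[[br$j]]
      base <- (f1 + f2) / sqrt(2)
      for (l in br$lnc)
        lnc[l, ] <- spec$corr_strength * base +
          spec$noise_sd / 2 * stats::rnorm(spec$n_samples)
    }
    lnc_mats[[d]] <- expression_matrix(lnc)
    mir_mats[[d]] <- expression_matrix(mir)
  }

  # --- interactions: planted + decoys ------------------------------------
  planted <- unique(do.call(rbind, c(
    lapply(diseases, function(d)
      expand.grid(mirna = mir_modules[[d]], lncrna = modules[[d]],
                  stringsAsFactors = FALSE)),
    lapply(seq_along(bg_mirs), function(i)
      expand.grid(mirna = bg_mirs[[i]], lncrna = bg_lncs[[i]],
                  stringsAsFactors = FALSE)),
    lapply(bridges, function(br)
      expand.grid(mirna = c(ring[[br$i]]$m, ring[[br$j]]$m),
                  lncrna = br$lnc, stringsAsFactors = FALSE)))))
  n_decoy <- round(spec$decoy_factor * nrow(planted))
  planted_key <- paste(planted$mirna, planted$lncrna, sep = "\r")
  decoys <- data.frame(mirna = character(0L), lncrna = character(0L))
  if (n_decoy > 0L) {
    got <- character(0L)
    while (length(got) < n_decoy) {
      cand <- paste(sample(mir_ids, n_decoy, replace = TRUE),
                    sample(lnc_ids, n_decoy, replace = TRUE), sep = "\r")
      got <- unique(c(got, setdiff(cand, planted_key)))
    }
    got <- got[seq_len(n_decoy)]
    parts <- strsplit(got, "\r", fixed = TRUE)
    decoys <- data.frame(mirna = vapply(parts, `[`, "", 1L),
                         lncrna = vapply(parts, `[`, "", 2L),
                         stringsAsFactors = FALSE)
  }
  interactions <- interaction_set(c(planted$mirna, decoys$mirna),
                                  c(planted$lncrna, decoys$lncrna))

  # --- seeds, phenotype ---------------------------------------------------
  # Per block, a pool of recurring known lncRNAs inside the shared core;
  # each disease draws most of its seeds from the pool (so seed sets of
  # related diseases overlap, as in curated corpora) and the rest from its
  # own module.
  seeds <- stats::setNames(vector("list", spec$n_diseases), diseases)
  n_pooled <- ceiling(spec$seeds_per_disease * 2 / 3)
  for (b in spec$phenotype_blocks) {
    ds <- diseases[b]
    core <- Reduce(intersect, modules[ds])
    pool_known <- if (length(core) > 0L)
      sample(core, min(spec$seeds_per_disease + 2L, length(core)))
    else character(0L)
    for (d in ds) {
      k <- min(n_pooled, length(pool_known))
      from_pool <- if (k > 0L) sample(pool_known, k) else character(0L)
      rest <- setdiff(modules[[d]], from_pool)
      seeds[[d]] <- c(from_pool,
                      sample(rest, spec$seeds_per_disease - k))
    }
  }
  P <- matrix(spec$between_block_sim, spec$n_diseases, spec$n_diseases,
              dimnames = list(diseases, diseases))
  for (b in spec$phenotype_blocks)
    P[diseases[b], diseases[b]] <- spec$within_block_sim
  diag(P) <- 1
  truth <- list(modules = modules, mirna_modules = mir_modules,
                background_mirnas = bg_mirs, background_lncrnas = bg_lncs,
                bridge_lncrnas = unlist(lapply(bridges, `[[`, "lnc"),
                                        use.names = FALSE),
                planted_pairs = planted,
                true_disease_lncrnas = seeds,
                blocks = lapply(spec$phenotype_blocks,
                                function(b) diseases[b]))
  structure(list(lncrna = lnc_mats, mirna = mir_mats,
                 interactions = interactions, seeds = seeds,
                 phenotype = phenotype_similarity(P), truth = truth,
                 spec = spec),
            class = "lncprop_corpus")
}

#' @export
print.lncprop_corpus <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic corpus: %d disease(s), %d lncRNAs x %d samples, %d miRNAs\n",
              s$n_diseases, s$n_lncrna, s$n_samples, s$n_mirna))
  cat(sprintf("  interactions: %d; seeds per disease: %d; blocks: %s\n",
              nrow(x$interactions), s$seeds_per_disease,
              paste(vapply(x$truth$blocks, paste, "", collapse = "+"),
                    collapse = " | ")))
  invisible(x)
}

#' Write a corpus to disk in the pipeline's input formats
#'
#' Emits, under `dir`: `<disease>_lncrna.tsv` / `<disease>_mirna.tsv`
#' expression TSVs, `interactions.tsv`, `seeds.tsv`, `phenotype.tsv`, and
#' `truth.json`.
#'
#' @param corpus A `"lncprop_corpus"` from [generate_corpus()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in names(corpus$lncrna)) {
    write_expression(corpus$lncrna[[d]], file.path(dir, paste0(d, "_lncrna.tsv")))
    write_expression(corpus$mirna[[d]], file.path(dir, paste0(d, "_mirna.tsv")))
  }
  write_interactions(corpus$interactions, file.path(dir, "interactions.tsv"))
  write_seeds(corpus$seeds, file.path(dir, "seeds.tsv"))
  write_phenotype_matrix(corpus$phenotype, file.path(dir, "phenotype.tsv"))
  jsonlite::write_json(corpus$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' A tiny fixed 2-disease instance with a fully enumerable expected network
#'
#' Hand-sized: 12 lncRNAs, 7 miRNAs, 10 samples per disease. Each disease
#' has a 5-lncRNA module driven by 3 miRNAs plus four filler partner pairs
#' that widen the miRNA universe to 7, so every module edge has
#' x = K = M = 3, N = 7 and the exactly enumerable p-value
#' C(3,3) C(4,0) / C(7,3) = 1/35, strictly inside the default edge FDR
#' threshold. The two modules overlap in L04/L05, which carry cross-disease
#' signal; the phenotype similarity between the two diseases is 0.6.
#' The shared module lncRNA L04 is a known seed of both diseases, so
#' holding it out for one disease leaves cross-disease evidence in place --
#' the transfer mechanism the integration exists for. Deterministic: built
#' from a fixed internal seed.
#'
#' @return A `"lncprop_corpus"`.
#' @export
worked_fixture <- function() {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(197001L)
  n <- 10L
  lnc_ids <- sprintf("L%02d", 1:12)
  mir_ids <- sprintf("MIR%d", 1:7)
  make_disease <- function(d, module_mirs, module_lncs, filler) {
    samples <- sprintf("%s_S%02d", d, seq_len(n))
    mir <- matrix(stats::rnorm(7 * n), nrow = 7,
                  dimnames = list(mir_ids, samples))
    lnc <- matrix(stats::rnorm(12 * n), nrow = 12,
                  dimnames = list(lnc_ids, samples))
    g <- stats::rnorm(n)
    for (m in module_mirs) mir[m, ] <- g + 0.05 * stats::rnorm(n)
    for (l in module_lncs) lnc[l, ] <- g + 0.05 * stats::rnorm(n)
    for (i in seq_along(filler$mir)) {
      h <- stats::rnorm(n)
      mir[filler$mir[i], ] <- h + 0.05 * stats::rnorm(n)
      lnc[filler$lnc[i], ] <- h + 0.05 * stats::rnorm(n)
    }
    list(mir = expression_matrix(mir), lnc = expression_matrix(lnc))
  }
  d1 <- make_disease("D1", c("MIR1", "MIR2", "MIR3"),
                     sprintf("L%02d", 1:5),
                     list(mir = c("MIR4", "MIR5", "MIR6", "MIR7"),
                          lnc = c("L09", "L10", "L11", "L12")))
  d2 <- make_disease("D2", c("MIR5", "MIR6", "MIR7"),
                     sprintf("L%02d", 4:8),
                     list(mir = c("MIR1", "MIR2", "MIR3", "MIR4"),
                          lnc = c("L09", "L10", "L11", "L12")))
  planted <- rbind(
    expand.grid(mirna = c("MIR1", "MIR2", "MIR3"),
                lncrna = sprintf("L%02d", 1:5), stringsAsFactors = FALSE),
    expand.grid(mirna = c("MIR5", "MIR6", "MIR7"),
                lncrna = sprintf("L%02d", 4:8), stringsAsFactors = FALSE),
    data.frame(mirna = c("MIR4", "MIR5", "MIR6", "MIR7",
                         "MIR1", "MIR2", "MIR3", "MIR4"),
               lncrna = rep(c("L09", "L10", "L11", "L12"), 2L),
               stringsAsFactors = FALSE),
    data.frame(mirna = c("MIR5", "MIR1"), lncrna = c("L01", "L06"),
               stringsAsFactors = FALSE))
  interactions <- interaction_set(planted$mirna, planted$lncrna)
  seeds <- list(D1 = c("L01", "L02", "L04"), D2 = c("L04", "L06", "L07"))
  P <- matrix(c(1, 0.6, 0.6, 1), 2, 2, dimnames = list(c("D1", "D2"),
                                                       c("D1", "D2")))
  truth <- list(modules = list(D1 = sprintf("L%02d", 1:5),
                               D2 = sprintf("L%02d", 4:8)),
                mirna_modules = list(D1 = c("MIR1", "MIR2", "MIR3"),
                                     D2 = c("MIR5", "MIR6", "MIR7")),
                shared = c("L04", "L05"))
  structure(list(lncrna = list(D1 = d1$lnc, D2 = d2$lnc),
                 mirna = list(D1 = d1$mir, D2 = d2$mir),
                 interactions = interactions, seeds = seeds,
                 phenotype = phenotype_similarity(P), truth = truth,
                 spec = NULL),
            class = "lncprop_corpus")
}
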