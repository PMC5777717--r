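#' Control parameters for the prioritization pipeline
#'
#' Collects every tunable knob of the pipeline in one validated list, in the
#' spirit of [glm.control()]. All stages take a `lncprop_control` object; the
#' defaults reproduce the standard analysis.
#'
#' @param fdr_coexpr BH-adjusted significance threshold for miRNA-lncRNA
#'   co-expression (default 0.05).
#' @param fdr_edge BH-adjusted significance threshold for lncRNA-lncRNA
#'   shared-partner edges (default 0.05).
#' @param restart_prob Restart probability `r` of the random walk, in (0, 1].
#'   Default 0.7, the usual convention in network-based disease-gene
#'   prioritization.
#' @param rwr_tol L1 convergence tolerance of the walk iteration.
#' @param rwr_max_iter Maximum number of power iterations.
#' @param universe_mode How the hypergeometric universe size N is chosen:
#'   `"observed_mirnas"` (default) uses the number of distinct miRNAs in the
#'   disease's partner map; `"fixed_value"` uses `fixed_N`.
#' @param fixed_N Universe size when `universe_mode = "fixed_value"`.
#' @param corr_sign Which co-expression signs count as evidence: `"both"`
#'   (default), `"positive"` or `"negative"`.
#' @param tail Hypergeometric tail convention: `"geq"` (default) tests
#'   P(X >= x), the standard enrichment tail; `"gt"` tests P(X > x).
#' @param norm Adjacency normalization for the walk: `"column"`
#'   (random-walk convention, default) or `"symmetric"`.
#' @param row_normalize_P If `TRUE`, rows of the phenotype similarity matrix
#'   are rescaled to sum to 1 before integration (sensitivity analysis only;
#'   default `FALSE`, i.e. the raw bilinear form).
#' @param permute Phenotype permutation scheme used by [permute_phenotype()]:
#'   `"offdiag"` (default) permutes the upper-triangle values and mirrors
#'   them; `"rowwise"` permutes entries within each row and re-symmetrizes.
#' @param rng_seed Integer seed used by the stochastic evaluation experiments
#'   and the synthetic generator; `NULL` leaves the RNG state alone.
#'
#' @return A list of class `"lncprop_control"`.
#' @examples
#' ctl <- lncprop_control(restart_prob = 0.5)
#' ctl$restart_prob
#' @export
lncprop_control <- function(fdr_coexpr = 0.05,
                            fdr_edge = 0.05,
                            restart_prob = 0.7,
                            rwr_tol = 1e-8,
                            rwr_max_iter = 1000L,
                            universe_mode = c("observed_mirnas", "fixed_value"),
                            fixed_N = NULL,
                            corr_sign = c("both", "positive", "negative"),
                            tail = c("geq", "gt"),
                            norm = c("column", "symmetric"),
                            row_normalize_P = FALSE,
                            permute = c("offdiag", "rowwise"),
                            rng_seed = NULL) {
  universe_mode <- match.arg(universe_mode)
  corr_sign <- match.arg(corr_sign)
  tail <- match.arg(tail)
  norm <- match.arg(norm)
  permute <- match.arg(permute)
  stopifnot(is.numeric(fdr_coexpr), length(fdr_coexpr) == 1L,
            fdr_coexpr > 0, fdr_coexpr <= 1)
  stopifnot(is.numeric(fdr_edge), length(fdr_edge) == 1L,
            fdr_edge > 0, fdr_edge <= 1)
  if (!is.numeric(restart_prob) || length(restart_prob) != 1L ||
      restart_prob <= 0 || restart_prob > 1)
    stop("'restart_prob' must lie in (0, 1]", call. = FALSE)
  stopifnot(is.numeric(rwr_tol), rwr_tol > 0)
  rwr_max_iter <- as.integer(rwr_max_iter)
  stopifnot(rwr_max_iter >= 1L)
  if (universe_mode == "fixed_value" &&
      (is.null(fixed_N) || !is.numeric(fixed_N) || fixed_N < 1))
    stop("universe_mode = 'fixed_value' requires a positive 'fixed_N'",
         call. = FALSE)
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  structure(list(fdr_coexpr = fdr_coexpr, fdr_edge = fdr_edge,
                 restart_prob = restart_prob, rwr_tol = rwr_tol,
                 rwr_max_iter = rwr_max_iter, universe_mode = universe_mode,
                 fixed_N = if (is.null(fixed_N)) NULL else as.integer(fixed_N),
                 corr_sign = corr_sign, tail = tail, norm = norm,
                 row_normalize_P = isTRUE(row_normalize_P), permute = permute,
                 rng_seed = rng_seed),
            class = "lncprop_control")
}

#' Read control parameters from a YAML file
#'
#' Every field is optional; omitted fields take the [lncprop_control()]
#' defaults. Unknown fields are an error, so typos never pass silently.
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [lncprop_control()].
#' @return A `"lncprop_control"` object.
#' @export
read_control <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- names(formals(lncprop_control))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(lncprop_control, cfg)
}

as_control <- function(control) {
  if (is.null(control)) return(lncprop_control())
  if (inherits(control, "lncprop_control")) return(control)
  if (is.list(control)) return(do.call(lncprop_control, control))
  stop("'control' must be a lncprop_control object or a list", call. = FALSE)
}
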