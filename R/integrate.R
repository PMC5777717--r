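# Cross-disease integration of propagation scores through the phenotype
# similarity matrix: S_ik = sum_j P_ij * S_jk, the raw bilinear form.

#' Integrate per-disease propagation scores across diseases
#'
#' For disease `i` and candidate lncRNA `k`, the integrated score is
#' `S_ik = sum_j P[i, j] * S[j, k]`, the sum running over every disease `j`
#' in the score table including `j = i` (the diagonal of `P` weights a
#' disease's own evidence). No rescaling of `P` or of the score rows is
#' applied unless `row_normalize_P = TRUE` (sensitivity analysis only).
#'
#' @param scores Disease-by-lncRNA score matrix from [score_table()].
#' @param P Phenotype similarity matrix whose labels cover the score table's
#'   diseases.
#' @param row_normalize_P Rescale each used row of `P` to sum to 1 first
#'   (default `FALSE`).
#' @return Matrix of integrated scores, same shape and dimnames as `scores`.
#' @export
integrate_scores <- function(scores, P, row_normalize_P = FALSE) {
  diseases <- rownames(scores)
  missing <- setdiff(diseases, rownames(P))
  if (length(missing) > 0L)
    stop("disease(s) missing from the phenotype matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  Psub <- P[diseases, diseases, drop = FALSE]
  if (all(diag(Psub) == 0) && length(diseases) > 1L)
    warning("phenotype matrix diagonal is zero: each disease's own evidence is discarded",
            call. = FALSE)
  if (isTRUE(row_normalize_P)) {
    rs <- rowSums(Psub)
    rs[rs == 0] <- 1
    Psub <- Psub / rs
  }
  Psub %*% scores
}

#' Rank candidate lncRNAs of one disease
#'
#' Descending by score; ties broken lexicographically by lncRNA id so the
#' ranking is deterministic. An optional exclusion list (e.g. a disease's own
#' remaining seeds during cross-validation) is removed before ranking.
#'
#' @param scores Named numeric score vector for one disease (a row of the
#'   integrated score matrix).
#' @param exclude Character vector of lncRNA ids removed from the candidate
#'   pool before ranking.
#' @return Data frame with columns `rank`, `lncrna`, `score` (rank 1 = best).
#' @export
rank_candidates <- function(scores, exclude = character(0L)) {
  if (length(scores) == 0L)
    stop("no candidates to rank", call. = FALSE)
  scores <- scores[!(names(scores) %in% exclude)]
  if (length(scores) == 0L)
    stop("exclusion list removed every candidate", call. = FALSE)
  ord <- order(-scores, names(scores))
  data.frame(rank = seq_along(ord), lncrna = names(scores)[ord],
             score = unname(scores)[ord], stringsAsFactors = FALSE)
}
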