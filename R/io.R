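# Plain-TSV readers/writers for every pipeline artifact. One dialect only:
# tab-separated, UTF-8, '.' decimal, no quoting. Strictness over guessing --
# ragged or non-numeric files are rejected with coordinates.

#' Construct a validated expression matrix
#'
#' A feature-by-sample numeric matrix (lncRNAs or miRNAs in rows, samples in
#' columns) with unique, non-empty row and column names and finite values.
#' Expression units are not interpreted; Pearson correlation is invariant to
#' linear rescaling of each feature.
#'
#' @param values Numeric matrix, features x samples.
#' @param feature_ids,sample_ids Optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return The validated matrix (a base `matrix` with dimnames).
#' @export
expression_matrix <- function(values, feature_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric", call. = FALSE)
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required", call. = FALSE)
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("identifier lengths do not match the matrix dimensions", call. = FALSE)
  check_unique_ids(feature_ids, "feature")
  check_unique_ids(sample_ids, "sample")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at feature '%s', sample '%s'",
                 feature_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  values
}

check_unique_ids <- function(ids, what) {
  if (any(!nzchar(ids)) || anyNA(ids))
    stop(sprintf("empty %s identifier", what), call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# Read a TSV into a character matrix, enforcing rectangular shape.
read_tsv_cells <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(NULL)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged TSV '%s': line %d has %d field(s), expected %d",
                 path, bad, widths[bad], widths[1L]), call. = FALSE)
  }
  do.call(rbind, cells)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and feature identifiers in the
#' first column. Row order is preserved. Duplicate identifiers, missing or
#' non-numeric cells, and ragged rows are format errors (no imputation).
#'
#' @param path Path to a TSV file.
#' @return A validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path) {
  cells <- read_tsv_cells(path)
  if (is.null(cells) || nrow(cells) < 2L || ncol(cells) < 2L)
    stop(sprintf("expression file '%s' needs a header row and at least one feature row",
                 path), call. = FALSE)
  sample_ids <- cells[1L, -1L]
  feature_ids <- cells[-1L, 1L]
  raw <- cells[-1L, -1L, drop = FALSE]
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' in '%s' at feature '%s' (row %d), sample '%s' (column %d)",
                 raw[bad[1L], bad[2L]], path, feature_ids[bad[1L]],
                 bad[1L] + 1L, sample_ids[bad[2L]], bad[2L] + 1L),
         call. = FALSE)
  }
  expression_matrix(values, feature_ids, sample_ids)
}

#' Write an expression matrix as TSV
#'
#' @param x Expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  header <- paste(c("feature_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format_num(x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

format_num <- function(x) {
  formatC(x, format = "g", digits = 15)
}

#' Construct a validated miRNA-lncRNA interaction set
#'
#' The experimentally validated interaction prior that gates co-expression
#' evidence. Duplicate pairs are collapsed.
#'
#' @param mirna,lncrna Character vectors of equal length.
#' @return A data frame with columns `mirna` and `lncrna`, one row per
#'   distinct pair, of class `c("interaction_set", "data.frame")`.
#' @export
interaction_set <- function(mirna, lncrna) {
  mirna <- as.character(mirna)
  lncrna <- as.character(lncrna)
  stopifnot(length(mirna) == length(lncrna))
  if (length(mirna) > 0L && (any(!nzchar(mirna)) || any(!nzchar(lncrna)) ||
                             anyNA(mirna) || anyNA(lncrna)))
    stop("interaction identifiers must be non-empty strings", call. = FALSE)
  key <- paste(mirna, lncrna, sep = "\r")
  keep <- !duplicated(key)
  ndup <- sum(!keep)
  if (ndup > 0L)
    message(sprintf("collapsed %d duplicate interaction pair(s)", ndup))
  out <- data.frame(mirna = mirna[keep], lncrna = lncrna[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' Read a validated miRNA-lncRNA interaction list from a 2-column TSV
#'
#' An optional header line is detected by name sniffing (first line whose
#' fields look like column labels such as `mirna`/`lncrna`). Duplicate rows
#' are collapsed with a message; an empty file yields an empty set with a
#' warning.
#'
#' @param path Path to a 2-column TSV (miRNA id, lncRNA id).
#' @return An `interaction_set` data frame.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning(sprintf("interaction file '%s' is empty", path), call. = FALSE)
    return(interaction_set(character(0L), character(0L)))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != 2L)) {
    bad <- which(widths != 2L)[1L]
    stop(sprintf("interaction file '%s': line %d has %d column(s), expected 2",
                 path, bad, widths[bad]), call. = FALSE)
  }
  first <- tolower(gsub("[^a-z]", "", tolower(cells[[1L]])))
  header_names <- c("mirna", "mirnaid", "mir", "lncrna", "lncrnaid", "lnc")
  if (all(first %in% header_names)) cells <- cells[-1L]
  if (length(cells) == 0L) {
    warning(sprintf("interaction file '%s' holds a header but no pairs", path),
            call. = FALSE)
    return(interaction_set(character(0L), character(0L)))
  }
  m <- do.call(rbind, cells)
  interaction_set(m[, 1L], m[, 2L])
}

#' Write an interaction set as a 2-column TSV
#' @param x An `interaction_set`.
#' @param path Output path.
#' @param header Write a `mirna&#9;lncrna` header line (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path, header = TRUE) {
  body <- paste(x$mirna, x$lncrna, sep = "\t")
  if (header) body <- c("mirna\tlncrna", body)
  writeLines(body, path, useBytes = TRUE)
  invisible(path)
}

#' Read per-disease seed lncRNA sets
#'
#' Seeds are the curated known disease lncRNAs that initialize propagation.
#' Format: 2-column TSV `(disease_id, lncrna_id)`, one pair per row, optional
#' header. A disease may legitimately have an empty seed set (it is then
#' scored purely through phenotype integration), but such diseases simply do
#' not appear in the file.
#'
#' @param path Path to the TSV.
#' @return A named list of character vectors (disease id -> seed lncRNAs).
#' @export
read_seeds <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning(sprintf("seed file '%s' is empty", path), call. = FALSE)
    return(structure(list(), names = character(0L)))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != 2L)) {
    bad <- which(widths != 2L)[1L]
    stop(sprintf("seed file '%s': line %d has %d column(s), expected 2",
                 path, bad, widths[bad]), call. = FALSE)
  }
  first <- gsub("[^a-z]", "", tolower(cells[[1L]]))
  if (all(first %in% c("disease", "diseaseid", "lncrna", "lncrnaid")))
    cells <- cells[-1L]
  m <- do.call(rbind, cells)
  split(m[, 2L], factor(m[, 1L], levels = unique(m[, 1L]))) |>
    lapply(unique)
}

#' Write per-disease seed sets as a 2-column TSV
#' @param seeds Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path) {
  rows <- unlist(lapply(names(seeds), function(d) {
    if (length(seeds[[d]]) == 0L) return(character(0L))
    paste(d, seeds[[d]], sep = "\t")
  }), use.names = FALSE)
  writeLines(c("disease\tlncrna", rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a disease phenotype similarity matrix
#'
#' A square labeled TSV of non-negative similarities (here typically derived
#' from Human Phenotype Ontology term overlap). Row and column labels must
#' match; asymmetry beyond 1e-9 is repaired by averaging `(P + t(P))/2` with
#' a warning.
#'
#' @param path Path to the TSV (header = disease ids, first column =
#'   disease ids).
#' @return A symmetric numeric matrix with disease ids as dimnames.
#' @export
read_phenotype_matrix <- function(path) {
  cells <- read_tsv_cells(path)
  if (is.null(cells) || nrow(cells) < 2L)
    stop(sprintf("phenotype file '%s' is empty", path), call. = FALSE)
  col_ids <- cells[1L, -1L]
  row_ids <- cells[-1L, 1L]
  if (length(col_ids) != length(row_ids))
    stop(sprintf("phenotype matrix in '%s' is not square (%d rows, %d columns)",
                 path, length(row_ids), length(col_ids)), call. = FALSE)
  if (!identical(as.character(col_ids), as.character(row_ids)))
    stop(sprintf("phenotype matrix labels mismatch in '%s': rows (%s) vs columns (%s)",
                 path, paste(row_ids, collapse = ","),
                 paste(col_ids, collapse = ",")), call. = FALSE)
  raw <- cells[-1L, -1L, drop = FALSE]
  P <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(P)) {
    bad <- which(is.na(P), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric phenotype similarity at (%s, %s) in '%s'",
                 row_ids[bad[1L]], col_ids[bad[2L]], path), call. = FALSE)
  }
  dimnames(P) <- list(row_ids, col_ids)
  phenotype_similarity(P)
}

#' Construct a validated phenotype similarity matrix
#'
#' @param P Square numeric matrix with matching dimnames; entries must be
#'   non-negative. Asymmetry beyond 1e-9 is symmetrized by averaging, with a
#'   warning.
#' @return The validated symmetric matrix.
#' @export
phenotype_similarity <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P))
    stop("phenotype similarity matrix is not square", call. = FALSE)
  if (is.null(rownames(P)) || is.null(colnames(P)) ||
      !identical(rownames(P), colnames(P)))
    stop("phenotype similarity matrix needs matching row/column labels",
         call. = FALSE)
  check_unique_ids(rownames(P), "disease")
  if (!all(is.finite(P)) || any(P < 0))
    stop("phenotype similarities must be finite and non-negative",
         call. = FALSE)
  asym <- max(abs(P - t(P)))
  if (asym > 1e-9) {
    warning(sprintf("phenotype matrix asymmetric (max |P - t(P)| = %.3g); symmetrized by averaging",
                    asym), call. = FALSE)
  }
  (P + t(P)) / 2
}

#' Write a phenotype similarity matrix as a square labeled TSV
#' @param P Symmetric similarity matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_matrix <- function(P, path) {
  header <- paste(c("disease", colnames(P)), collapse = "\t")
  body <- vapply(seq_len(nrow(P)), function(i) {
    paste(c(rownames(P)[i], format_num(P[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a competing network edge list as TSV
#'
#' Six columns: `lncrna_a`, `lncrna_b`, `shared_mirnas`, `p`, `q`, `weight`;
#' pairs in lexicographic order, rows sorted by `q` then pair key, so output
#' is byte-reproducible.
#'
#' @param network A `competing_network` (see [build_network()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  e <- network$edges
  header <- "lncrna_a\tlncrna_b\tshared_mirnas\tp\tq\tweight"
  if (nrow(e) == 0L) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  ord <- order(e$q, e$lncrna_a, e$lncrna_b)
  e <- e[ord, , drop = FALSE]
  body <- paste(e$lncrna_a, e$lncrna_b, e$x,
                format_num(e$p), format_num(e$q), format_num(e$weight),
                sep = "\t")
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Read a competing network edge list written by [write_network()]
#' @param path Path to the 6-column TSV.
#' @param disease_id Disease label to attach (default: file stem).
#' @return A `competing_network` object.
#' @export
read_network <- function(path, disease_id = NULL) {
  if (is.null(disease_id))
    disease_id <- sub("[._-]?network$", "",
                      tools::file_path_sans_ext(basename(path)))
  cells <- read_tsv_cells(path)
  header <- c("lncrna_a", "lncrna_b", "shared_mirnas", "p", "q", "weight")
  if (is.null(cells) || !identical(unname(cells[1L, ]), header))
    stop(sprintf("'%s' is not a network edge-list TSV", path), call. = FALSE)
  if (nrow(cells) == 1L) {
    edges <- data.frame(lncrna_a = character(0L), lncrna_b = character(0L),
                        x = integer(0L), p = numeric(0L), q = numeric(0L),
                        weight = numeric(0L), stringsAsFactors = FALSE)
  } else {
    m <- cells[-1L, , drop = FALSE]
    edges <- data.frame(lncrna_a = m[, 1L], lncrna_b = m[, 2L],
                        x = as.integer(m[, 3L]), p = as.numeric(m[, 4L]),
                        q = as.numeric(m[, 5L]), weight = as.numeric(m[, 6L]),
                        stringsAsFactors = FALSE)
    if (anyNA(edges$x) || anyNA(edges$p) || anyNA(edges$q) || anyNA(edges$weight))
      stop(sprintf("non-numeric edge attribute in '%s'", path), call. = FALSE)
  }
  competing_network(disease_id, edges)
}

#' Write a per-disease score vector as TSV
#'
#' Two columns `(lncrna_id, score)`, sorted by descending score and then
#' lexicographically.
#' @param scores Named numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  ord <- order(-scores, names(scores))
  body <- paste(names(scores)[ord], format_num(unname(scores)[ord]), sep = "\t")
  writeLines(c("lncrna_id\tscore", body), path, useBytes = TRUE)
  invisible(path)
}

#' Write a ranked candidate list as TSV
#' @param ranked Data frame from [rank_candidates()].
#' @param path Output path.
#' @param disease Optional: prepend a disease column (long format).
#' @return `path`, invisibly.
#' @export
write_ranked <- function(ranked, path, disease = NULL) {
  if (is.null(disease)) {
    body <- paste(ranked$rank, ranked$lncrna, format_num(ranked$score),
                  sep = "\t")
    writeLines(c("rank\tlncrna_id\tscore", body), path, useBytes = TRUE)
  } else {
    body <- paste(disease, ranked$rank, ranked$lncrna,
                  format_num(ranked$score), sep = "\t")
    writeLines(c("disease\trank\tlncrna_id\tscore", body), path,
               useBytes = TRUE)
  }
  invisible(path)
}
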