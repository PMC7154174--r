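# Mutual exclusivity of somatic mutations. A gene set's exclusivity is
# its coverage (fraction of samples with >= 1 mutated member) minus its
# coverage overlap (fraction with >= 2 mutated members):
#   ME(se) = C(se) - O(se).

.check_genes <- function(M, genes) {
  if (length(genes) < 1L) stop("gene set must be non-empty")
  unknown <- setdiff(genes, colnames(M))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (nrow(M) < 1L) stop("mutation matrix has no samples")
  invisible(TRUE)
}

.set_counts <- function(M, genes) {
  rowSums(M[, genes, drop = FALSE])
}

#' Coverage of a gene set
#'
#' Fraction of samples carrying a mutation in at least one gene of the
#' set.
#'
#' @param M binary mutation matrix (samples x genes).
#' @param genes character vector of gene ids, a subset of `colnames(M)`.
#' @return coverage in \[0, 1\].
#' @export
coverage <- function(M, genes) {
  .check_genes(M, genes)
  sum(.set_counts(M, genes) >= 1L) / nrow(M)
}

#' Coverage overlap of a gene set
#'
#' Fraction of samples carrying mutations in two or more genes of the
#' set.
#'
#' @inheritParams coverage
#' @return overlap in \[0, 1\].
#' @export
coverage_overlap <- function(M, genes) {
  .check_genes(M, genes)
  sum(.set_counts(M, genes) >= 2L) / nrow(M)
}

#' Mutual exclusivity of a gene set
#'
#' `ME = coverage - overlap`, i.e. the fraction of samples with exactly
#' one mutated member. High ME marks sets whose members mutate in
#' different patients, the signature of a driver module.
#'
#' @inheritParams coverage
#' @return a `gene_set_stats` list with fields `genes`, `coverage`,
#'   `overlap`, `me`.
#' @export
mutex_score <- function(M, genes) {
  .check_genes(M, genes)
  counts <- .set_counts(M, genes)
  cv <- sum(counts >= 1L) / nrow(M)
  ov <- sum(counts >= 2L) / nrow(M)
  structure(list(genes = genes, coverage = cv, overlap = ov, me = cv - ov),
            class = "gene_set_stats")
}

#' Pairwise mutual exclusivity
#'
#' ME for unordered gene pairs: either all pairs among `genes` (returned
#' as a symmetric matrix with an `NA` diagonal) or an explicit set of
#' pairs (returned as a vector), e.g. the edges of a PPI network.
#'
#' @param M binary mutation matrix.
#' @param genes optional gene subset; defaults to all genes of `M`.
#' @param pairs optional two-column character matrix of gene pairs; when
#'   given, `genes` is ignored and a numeric vector (one ME per row of
#'   `pairs`) is returned.
#' @return symmetric numeric matrix, or numeric vector if `pairs` given.
#' @export
pairwise_mutex <- function(M, genes = NULL, pairs = NULL) {
  if (!is.null(pairs)) {
    pairs <- as.matrix(pairs)
    .check_genes(M, unique(as.vector(pairs)))
    A <- M[, pairs[, 1L], drop = FALSE] + M[, pairs[, 2L], drop = FALSE]
    return(colSums(A == 1L) / nrow(M))
  }
  if (is.null(genes)) genes <- colnames(M)
  .check_genes(M, genes)
  n <- length(genes)
  out <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  if (n >= 2L) {
    cmb <- utils::combn(n, 2L)
    me <- pairwise_mutex(M, pairs = cbind(genes[cmb[1L, ]], genes[cmb[2L, ]]))
    out[t(cmb)] <- me
    out[t(cmb)[, 2:1, drop = FALSE]] <- me
  }
  out
}
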