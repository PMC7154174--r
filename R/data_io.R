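# Readers and writers for the four on-disk artifacts:
#   mutation matrix (samples x genes TSV, or (sample, gene) pair list),
#   CCF matrix (same shape as the mutation matrix),
#   functional network (gene, gene, LS score edge list),
#   PPI network (gene, gene edge list),
# plus the module-result TSV.

#' Validate a binary mutation matrix
#'
#' Checks the container contract used throughout the package: an integer
#' matrix with samples as rows and genes as columns, entries in \{0, 1\},
#' and unique, non-empty dimnames.
#'
#' @param M matrix to validate.
#' @return `M`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_mutation_matrix <- function(M) {
  if (!is.matrix(M)) stop("mutation matrix must be a matrix")
  if (is.null(colnames(M)) || (nrow(M) > 0L && is.null(rownames(M))))
    stop("mutation matrix must carry sample rownames and gene colnames")
  if (anyDuplicated(rownames(M))) stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(M))) stop("duplicate gene identifiers")
  if (!all(M %in% c(0L, 1L))) stop("mutation matrix entries must all be 0 or 1")
  invisible(M)
}

#' Read a binary somatic mutation matrix
#'
#' Two dialects are supported. The canonical `"matrix"` dialect is a TSV
#' with a header row `sample<TAB>gene1<TAB>gene2...` and one row per
#' sample, entries 0/1. The `"pair-list"` dialect is a headerless
#' two-column TSV of (sample, gene) mutation events, as exported
#' per-mutation by cBioPortal-style portals; duplicate pairs collapse to
#' a single 1.
#'
#' @param path path to a TSV file.
#' @param dialect `"matrix"` (default) or `"pair-list"`.
#' @return integer matrix, samples x genes, entries in \{0, 1\}.
#' @export
read_mutation_matrix <- function(path, dialect = c("matrix", "pair-list")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "matrix") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             comment.char = "", quote = "")
    if (ncol(tab) < 1L) stop("format error: mutation matrix file has no columns")
    samples <- tab[[1L]]
    genes <- colnames(tab)[-1L]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(as.numeric(vals))
    bad <- is.na(num) | !(num %in% c(0, 1))
    if (any(bad)) {
      k <- which(bad)[1L]
      r <- (k - 1L) %% nrow(vals) + 1L
      cc <- (k - 1L) %/% nrow(vals) + 1L
      stop(sprintf("format error: non-binary entry '%s' (sample '%s', gene '%s')",
                   vals[k], samples[r], genes[cc]))
    }
    M <- matrix(as.integer(num), nrow = nrow(vals), ncol = length(genes),
                dimnames = list(samples, genes))
  } else {
    tab <- utils::read.table(path, header = FALSE, sep = "\t",
                             colClasses = "character", comment.char = "",
                             quote = "")
    if (ncol(tab) != 2L)
      stop("format error: pair-list dialect expects two columns, got ", ncol(tab))
    samples <- sort(unique(tab[[1L]]))
    genes <- sort(unique(tab[[2L]]))
    M <- matrix(0L, length(samples), length(genes),
                dimnames = list(samples, genes))
    M[cbind(match(tab[[1L]], samples), match(tab[[2L]], genes))] <- 1L
  }
  validate_mutation_matrix(M)
}

#' Write a mutation matrix to TSV (matrix dialect)
#'
#' Inverse of [read_mutation_matrix()]'s matrix dialect; a written matrix
#' reads back identically.
#'
#' @param M validated binary mutation matrix.
#' @param path output path.
#' @export
write_mutation_matrix <- function(M, path) {
  validate_mutation_matrix(M)
  df <- data.frame(sample = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Cancer Cell Fraction (CCF) matrix
#'
#' Same TSV layout as the mutation-matrix dialect. Entries must lie in
#' \[0, 1\]; cells without a mutation may be empty or `NA`.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, samples x genes, values in \[0, 1\] or `NA`.
#' @export
read_ccf_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "", quote = "",
                           na.strings = c("", "NA"))
  samples <- as.character(tab[[1L]])
  C <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(C) <- "double"
  rownames(C) <- samples
  bad <- !is.na(C) & (C < 0 | C > 1)
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("CCF value out of [0,1]: %s (sample '%s', gene '%s')",
                 C[k], rownames(C)[(k - 1L) %% nrow(C) + 1L],
                 colnames(C)[(k - 1L) %/% nrow(C) + 1L]))
  }
  C
}

#' Read a weighted gene functional interaction network
#'
#' Parses a HumanNet-style headerless three-column TSV
#' (geneA, geneB, log-likelihood score). Self-loop lines are skipped with
#' a warning; if the same unordered pair appears with different scores the
#' maximum is kept (with a warning).
#'
#' @param path path to the edge-list TSV.
#' @return undirected [igraph][igraph::graph_from_data_frame] graph with an
#'   `ls` edge attribute.
#' @export
read_functional_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "",
                           quote = "")
  if (ncol(tab) != 3L)
    stop("format error: functional network expects three columns, got ", ncol(tab))
  ls <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(ls) || any(!is.finite(ls)))
    stop("format error: non-numeric LS score at line ",
         which(is.na(ls) | !is.finite(ls))[1L])
  self <- tab[[1L]] == tab[[2L]]
  if (any(self)) {
    warning(sum(self), " self-loop line(s) skipped")
    tab <- tab[!self, , drop = FALSE]
    ls <- ls[!self]
  }
  a <- pmin(tab[[1L]], tab[[2L]])
  b <- pmax(tab[[1L]], tab[[2L]])
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    mx <- tapply(ls, key, max)
    mn <- tapply(ls, key, min)
    if (any(mx > mn))
      warning("duplicate edges with differing LS scores; keeping the maximum")
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
    ls <- as.numeric(mx[key[first]])
  }
  igraph::graph_from_data_frame(
    data.frame(from = a, to = b, ls = ls, stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Read an unweighted PPI network
#'
#' Parses a Multinet-style headerless two-column TSV edge list into a
#' simple undirected graph (duplicate edges and self-loops removed).
#'
#' @param path path to the edge-list TSV.
#' @return undirected igraph graph.
#' @export
read_ppi_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", comment.char = "",
                           quote = "")
  if (ncol(tab) != 2L)
    stop("format error: PPI network expects two columns, got ", ncol(tab))
  self <- tab[[1L]] == tab[[2L]]
  if (any(self)) {
    warning(sum(self), " self-loop line(s) skipped")
    tab <- tab[!self, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(tab, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write driver modules to TSV
#'
#' Columns: `rank`, `genes` (semicolon-joined, sorted), `size`, `me`,
#' `p_value`, `mean_ws`. Rows are ordered by ascending p-value, ties by
#' descending mean edge weight.
#'
#' @param modules a `driver_modules` list as returned by [refine_all()],
#'   or any list of module records with fields `genes`, `me`, `p_value`,
#'   `mean_ws`.
#' @param path output path.
#' @export
write_modules <- function(modules, path) {
  df <- as.data.frame.driver_modules(modules)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate driver modules
#'
#' @param x `driver_modules` list.
#' @param ... unused.
#' @return data.frame with one row per module, ordered by ascending
#'   p-value then descending mean edge weight.
#' @export
as.data.frame.driver_modules <- function(x, ...) {
  if (length(x) == 0L)
    return(data.frame(rank = integer(), genes = character(), size = integer(),
                      me = numeric(), p_value = numeric(), mean_ws = numeric(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    genes = vapply(x, function(m) paste(sort(m$genes), collapse = ";"), ""),
    size = vapply(x, function(m) length(m$genes), 0L),
    me = vapply(x, function(m) m$me, 0),
    p_value = vapply(x, function(m) m$p_value, 0),
    mean_ws = vapply(x, function(m) if (is.null(m$mean_ws) || is.na(m$mean_ws)) 0 else m$mean_ws, 0),
    stringsAsFactors = FALSE)
  df <- df[order(df$p_value, -df$mean_ws, df$genes), , drop = FALSE]
  cbind(rank = seq_len(nrow(df)), df, row.names = NULL)
}

#' @exportS3Method base::print
print.driver_modules <- function(x, ...) {
  cat(length(x), "driver module(s)\n")
  if (length(x)) print(as.data.frame(x))
  invisible(x)
}
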