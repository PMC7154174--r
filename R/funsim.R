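# Functional similarity of PPI nodes, derived from a weighted gene
# functional interaction network (HumanNet-style log-likelihood scores).
# LS scores are min-max normalized to [0,1]; pairwise gene similarity is
# the normalized score (1 on the diagonal, 0 for non-edges); similarity
# of two PPI nodes is the Best-Match Average over their PPI
# neighborhoods.

#' Min-max normalize a functional network
#'
#' Maps each edge's LS score to
#' `(LS - LS_min) / (LS_max - LS_min)`, where the extremes are taken over
#' the whole network. If every LS is identical the range is degenerate;
#' all normalized scores are then set to 1 with a warning.
#'
#' @param fn functional network as returned by
#'   [read_functional_network()] (igraph with an `ls` edge attribute).
#' @return a `norm_funnet` object holding the gene universe and a sparse
#'   symmetric matrix of normalized scores in \[0, 1\].
#' @export
normalize_ls <- function(fn) {
  ls <- igraph::E(fn)$ls
  if (is.null(ls) || length(ls) < 1L)
    stop("functional network has no LS-scored edges")
  rng <- range(ls)
  if (rng[1L] == rng[2L]) {
    warning("degenerate LS range (all scores equal); setting all LS_N = 1")
    lsn <- rep(1, length(ls))
  } else {
    lsn <- (ls - rng[1L]) / (rng[2L] - rng[1L])
  }
  genes <- igraph::V(fn)$name
  el <- igraph::as_edgelist(fn, names = FALSE)
  mat <- Matrix::sparseMatrix(i = c(el[, 1L], el[, 2L]),
                              j = c(el[, 2L], el[, 1L]),
                              x = c(lsn, lsn),
                              dims = c(length(genes), length(genes)),
                              dimnames = list(genes, genes))
  structure(list(genes = genes, mat = mat, ls_range = rng),
            class = "norm_funnet")
}

#' Pairwise gene similarity
#'
#' 1 if the genes are identical, the normalized LS score if they share a
#' functional-network edge, and 0 otherwise (including genes absent from
#' the network).
#'
#' @param nfn a `norm_funnet` from [normalize_ls()].
#' @param g_i,g_j gene ids.
#' @return similarity in \[0, 1\].
#' @export
gene_similarity <- function(nfn, g_i, g_j) {
  if (identical(g_i, g_j)) return(1)
  i <- match(g_i, nfn$genes)
  j <- match(g_j, nfn$genes)
  if (is.na(i) || is.na(j)) return(0)
  as.numeric(nfn$mat[i, j])
}

#' Similarity of a gene to a gene set
#'
#' Maximum of [gene_similarity()] over the members of `G`; equals 1
#' whenever `g_n` itself belongs to `G`.
#'
#' @param nfn a `norm_funnet`.
#' @param g_n gene id.
#' @param G non-empty character vector of gene ids.
#' @return similarity in \[0, 1\].
#' @export
gene_set_similarity <- function(nfn, g_n, G) {
  if (length(G) < 1L) stop("gene set G must be non-empty")
  .set_sim_vec(nfn, g_n, G)
}

# vectorized S(g, G) for each g in gs; self-membership gives 1
.set_sim_vec <- function(nfn, gs, G) {
  out <- numeric(length(gs))
  out[gs %in% G] <- 1
  todo <- which(out < 1)
  if (length(todo)) {
    gi <- match(gs[todo], nfn$genes)
    Gi <- match(G, nfn$genes)
    Gi <- Gi[!is.na(Gi)]
    ok <- !is.na(gi)
    if (length(Gi) && any(ok)) {
      sub <- as.matrix(nfn$mat[gi[ok], Gi, drop = FALSE])
      out[todo[ok]] <- apply(sub, 1L, max)
    }
  }
  out
}

.ppi_neighbors <- function(ppi, g) {
  v <- igraph::V(ppi)$name
  if (!(g %in% v)) stop("gene '", g, "' not in the PPI network")
  nb <- igraph::neighbors(ppi, g)$name
  setdiff(nb, g)
}

# core BMA on explicit neighbor sets
.bma_core <- function(nfn, Gi, Gj) {
  (sum(.set_sim_vec(nfn, Gi, Gj)) + sum(.set_sim_vec(nfn, Gj, Gi))) /
    (length(Gi) + length(Gj))
}

#' Best-Match Average (BMA) functional similarity of two PPI nodes
#'
#' Each PPI neighbor of one node is matched to its most similar gene in
#' the other node's neighborhood; the matches of both directions are
#' averaged:
#' `S^P_ij = (sum_{g in G_i} S(g, G_j) + sum_{g in G_j} S(g, G_i)) / (|G_i| + |G_j|)`,
#' where `G_i` is the set of PPI neighbors of `pg_i` (the node itself
#' excluded). Symmetric and bounded in \[0, 1\]; a node with no PPI
#' neighbors yields 0 with a warning.
#'
#' @param nfn a `norm_funnet`.
#' @param ppi undirected PPI igraph.
#' @param pg_i,pg_j PPI node ids.
#' @return similarity in \[0, 1\].
#' @export
bma_similarity <- function(nfn, ppi, pg_i, pg_j) {
  Gi <- .ppi_neighbors(ppi, pg_i)
  Gj <- .ppi_neighbors(ppi, pg_j)
  if (!length(Gi) || !length(Gj)) {
    warning("node with no PPI neighbors; similarity defined as 0")
    return(0)
  }
  .bma_core(nfn, Gi, Gj)
}
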