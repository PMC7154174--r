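# Weighted PPI graph construction: edge weight ws = ME x S^P, the
# product of pairwise mutual exclusivity and BMA functional similarity,
# computed for PPI edges between mutated genes.

#' Build the exclusivity-weighted PPI graph
#'
#' Restricts the PPI network to genes of the (CCF-filtered) mutation
#' matrix, then weights every remaining PPI edge by
#' `ws(pg_i, pg_j) = ME(pg_i, pg_j) * S^P(pg_i, pg_j)`. BMA neighborhoods
#' are taken from the full PPI network. Zero-weight edges are removed;
#' isolated nodes are retained (they surface as singleton clusters and
#' are discarded during refinement). Genes never mutated, or mutated but
#' absent from the PPI, are excluded with a message.
#'
#' @param M binary mutation matrix (CCF-filtered if filtering is on).
#' @param ppi undirected PPI igraph.
#' @param nfn normalized functional network from [normalize_ls()].
#' @return undirected igraph over the mutated-and-in-PPI genes with a
#'   `weight` edge attribute in \(0, 1\].
#' @export
build_weighted_graph <- function(M, ppi, nfn) {
  validate_mutation_matrix(M)
  genes <- colnames(M)[colSums(M) > 0L]
  nodes <- intersect(genes, igraph::V(ppi)$name)
  if (!length(nodes))
    stop("no mutated gene is present in the PPI network")
  dropped <- setdiff(genes, nodes)
  if (length(dropped))
    message(length(dropped), " mutated gene(s) absent from the PPI network excluded")
  sub <- igraph::induced_subgraph(ppi, nodes)
  el <- igraph::as_edgelist(sub, names = TRUE)
  wdf <- NULL
  if (nrow(el)) {
    me <- pairwise_mutex(M, pairs = el)
    # neighborhoods from the full PPI, cached per node
    touched <- unique(as.vector(el))
    nbrs <- lapply(igraph::adjacent_vertices(ppi, touched), function(v) v$name)
    names(nbrs) <- touched
    sp <- vapply(seq_len(nrow(el)), function(k) {
      Gi <- setdiff(nbrs[[el[k, 1L]]], el[k, 1L])
      Gj <- setdiff(nbrs[[el[k, 2L]]], el[k, 2L])
      if (!length(Gi) || !length(Gj)) return(0)
      .bma_core(nfn, Gi, Gj)
    }, numeric(1L))
    ws <- me * sp
    keep <- ws > 0
    wdf <- data.frame(from = el[keep, 1L], to = el[keep, 2L],
                      weight = ws[keep], stringsAsFactors = FALSE)
  }
  if (is.null(wdf) || nrow(wdf) == 0L)
    wdf <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(wdf, directed = FALSE,
                                vertices = data.frame(name = nodes))
}
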