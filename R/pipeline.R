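# End-to-end driver-module detection: optional CCF filtering, edge
# weighting, Markov clustering, permutation-test refinement.

#' Identify cancer driver modules
#'
#' Runs the full pipeline on a binary mutation matrix, a PPI network and
#' a weighted functional network: (1) optionally sharpen the mutation
#' matrix with CCF values ([filter_mutations()]); (2) normalize the
#' functional scores ([normalize_ls()]) and weight each PPI edge between
#' mutated genes by exclusivity times BMA functional similarity
#' ([build_weighted_graph()]); (3) extract candidate modules by Markov
#' clustering ([run_mcl()]); (4) refine candidates with a permutation
#' test on group exclusivity ([refine_all()]).
#'
#' @param M binary mutation matrix (samples x genes).
#' @param ppi undirected PPI igraph.
#' @param nf functional network igraph with an `ls` edge attribute, or a
#'   pre-normalized `norm_funnet`.
#' @param ccf optional CCF matrix aligned to `M`.
#' @param ccf_cfg a [ccf_filter_config()]; used only when `ccf` is given.
#' @param mcl_cfg an [mcl_config()].
#' @param perm_cfg a [permutation_config()].
#' @param min_module_size smallest admissible module; default 3.
#' @param max_exhaustive see [refine_cluster()]; default 12.
#' @return a `driver_modules` list (see [refine_all()]), with the
#'   weighted graph and clustering attached as attributes `wgraph` and
#'   `clustering`.
#' @export
find_driver_modules <- function(M, ppi, nf, ccf = NULL,
                                ccf_cfg = ccf_filter_config(),
                                mcl_cfg = mcl_config(),
                                perm_cfg = permutation_config(),
                                min_module_size = 3L,
                                max_exhaustive = 12L) {
  if (!is.null(ccf)) M <- filter_mutations(M, ccf, ccf_cfg)
  nfn <- if (inherits(nf, "norm_funnet")) nf else normalize_ls(nf)
  g <- build_weighted_graph(M, ppi, nfn)
  cl <- run_mcl(g, mcl_cfg)
  mods <- refine_all(M, cl, perm_cfg, wgraph = g,
                     min_module_size = min_module_size,
                     max_exhaustive = max_exhaustive)
  attr(mods, "wgraph") <- g
  attr(mods, "clustering") <- cl
  mods
}
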