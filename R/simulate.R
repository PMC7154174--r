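# Synthetic benchmark data: mutation matrices with planted mutually
# exclusive driver modules, symmetric flip noise and passenger genes,
# plus companion PPI and functional networks in which planted-module
# genes are interconnected. The defaults mirror the benchmark
# conditions: 500 patients, 200 mutant genes, flip noise in 0.05-0.11.

#' Simulation configuration
#'
#' @param n_samples number of patients; default 500.
#' @param n_genes number of genes; default 200.
#' @param n_modules number of planted modules (1-4); default 1.
#' @param module_sizes integer vector of planted-module sizes; default 4
#'   genes each.
#' @param module_coverage total fraction of samples covered by planted
#'   modules; each module covers
#'   `floor(module_coverage * n_samples / n_modules)` distinct samples.
#'   Default 0.9.
#' @param noise probability of flipping each matrix cell (0 -> 1 or
#'   1 -> 0); default 0.05.
#' @param passenger_rate per-cell mutation probability of non-planted
#'   (passenger) genes before noise; default 0.05.
#' @param ppi_bg_p Erdős–Rényi edge probability among background genes
#'   in the companion PPI; default 0.05.
#' @param ls_module_range LS range (uniform) for functional-network
#'   edges inside planted cliques; default c(4, 6).
#' @param ls_bg_range LS range for background edges; default c(0, 2).
#' @param seed optional integer seed; generation is bit-reproducible
#'   given the seed and leaves the caller's RNG state untouched.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 500L, n_genes = 200L, n_modules = 1L,
                       module_sizes = rep(4L, n_modules),
                       module_coverage = 0.9, noise = 0.05,
                       passenger_rate = 0.05, ppi_bg_p = 0.05,
                       ls_module_range = c(4, 6), ls_bg_range = c(0, 2),
                       seed = NULL) {
  n_samples <- as.integer(n_samples); n_genes <- as.integer(n_genes)
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes) != n_modules)
    stop("module_sizes must have n_modules entries")
  if (any(module_sizes < 2L)) stop("module sizes must be >= 2")
  if (sum(module_sizes) > n_genes)
    stop("sum of module sizes exceeds n_genes")
  if (noise < 0 || noise >= 0.5) stop("noise must be in [0, 0.5)")
  if (passenger_rate < 0 || passenger_rate >= 0.5)
    stop("passenger_rate must be in [0, 0.5)")
  if (module_coverage <= 0 || module_coverage > 1)
    stop("module_coverage must be in (0, 1]")
  cov_per <- floor(module_coverage * n_samples / n_modules)
  if (any(cov_per < module_sizes))
    stop("covered samples per module fewer than the module size")
  structure(list(n_samples = n_samples, n_genes = n_genes,
                 n_modules = as.integer(n_modules),
                 module_sizes = module_sizes,
                 module_coverage = module_coverage, noise = noise,
                 passenger_rate = passenger_rate, ppi_bg_p = ppi_bg_p,
                 ls_module_range = ls_module_range,
                 ls_bg_range = ls_bg_range, seed = seed),
            class = "sim_config")
}

#' Generate a simulated dataset with planted exclusive modules
#'
#' Construction: (1) each planted module receives a disjoint block of
#' `floor(module_coverage * n_samples / n_modules)` covered samples and
#' each covered sample is assigned exactly one of the module's genes
#' (round-robin), so planted columns are perfectly mutually exclusive
#' before noise; (2) passenger-gene cells are i.i.d.
#' Bernoulli(`passenger_rate`); (3) every cell is flipped independently
#' with probability `noise`. Companion networks: planted-module genes
#' form PPI cliques with high functional scores
#' (LS ~ Uniform over `ls_module_range`); background genes receive
#' Erdős–Rényi PPI edges among themselves (probability `ppi_bg_p`) with
#' low scores (LS ~ Uniform over `ls_bg_range`). The functional network
#' shares the PPI topology.
#'
#' @param cfg a [sim_config()].
#' @return a `sim_dataset` list: `M` (mutation matrix), `truth` (list of
#'   planted gene sets), `ppi`, `nf` (igraphs), `pre_noise` (matrix
#'   before the flip step), `config`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_local_seed(cfg$seed, {
    n <- cfg$n_samples; p <- cfg$n_genes
    samples <- sprintf("s%04d", seq_len(n))
    genes <- sprintf("g%04d", seq_len(p))
    planted_idx <- sample.int(p, sum(cfg$module_sizes))
    truth <- split(genes[planted_idx],
                   rep(seq_len(cfg$n_modules), cfg$module_sizes))
    truth <- lapply(unname(truth), sort)
    bg <- setdiff(genes, genes[planted_idx])

    M <- matrix(0L, n, p, dimnames = list(samples, genes))
    cov_per <- floor(cfg$module_coverage * n / cfg$n_modules)
    covered <- sample.int(n, cov_per * cfg$n_modules)
    for (m in seq_len(cfg$n_modules)) {
      cs <- covered[((m - 1L) * cov_per + 1L):(m * cov_per)]
      gs <- truth[[m]]
      gcol <- gs[(seq_along(cs) - 1L) %% length(gs) + 1L]
      M[cbind(cs, match(gcol, genes))] <- 1L
    }
    if (length(bg) && cfg$passenger_rate > 0)
      M[, bg] <- matrix(stats::rbinom(n * length(bg), 1L, cfg$passenger_rate),
                        n, length(bg))
    pre_noise <- M
    if (cfg$noise > 0) {
      flip <- matrix(stats::runif(n * p) < cfg$noise, n, p)
      M[flip] <- 1L - M[flip]
    }

    edges <- list()
    for (gs in truth) {
      cmb <- utils::combn(gs, 2L)
      edges[[length(edges) + 1L]] <-
        data.frame(from = cmb[1L, ], to = cmb[2L, ],
                   ls = stats::runif(ncol(cmb), cfg$ls_module_range[1L],
                                     cfg$ls_module_range[2L]),
                   stringsAsFactors = FALSE)
    }
    if (length(bg) >= 2L && cfg$ppi_bg_p > 0) {
      cmb <- utils::combn(bg, 2L)
      pick <- stats::runif(ncol(cmb)) < cfg$ppi_bg_p
      if (any(pick))
        edges[[length(edges) + 1L]] <-
          data.frame(from = cmb[1L, pick], to = cmb[2L, pick],
                     ls = stats::runif(sum(pick), cfg$ls_bg_range[1L],
                                       cfg$ls_bg_range[2L]),
                     stringsAsFactors = FALSE)
    }
    edf <- do.call(rbind, edges)
    verts <- data.frame(name = genes, stringsAsFactors = FALSE)
    ppi <- igraph::graph_from_data_frame(edf[, c("from", "to")],
                                         directed = FALSE, vertices = verts)
    nf <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                        vertices = verts)
    structure(list(M = M, truth = truth, ppi = ppi, nf = nf,
                   pre_noise = pre_noise, config = cfg),
              class = "sim_dataset")
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits the standard TSV inputs (`mutations.tsv`, `ppi.tsv`,
#' `functional_network.tsv`) plus `truth.tsv` (module, gene).
#'
#' @param ds a `sim_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mutation_matrix(ds$M, file.path(dir, "mutations.tsv"))
  el <- igraph::as_edgelist(ds$ppi)
  utils::write.table(el, file.path(dir, "ppi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  nel <- cbind(as.data.frame(igraph::as_edgelist(ds$nf),
                             stringsAsFactors = FALSE),
               ls = igraph::E(ds$nf)$ls)
  utils::write.table(nel, file.path(dir, "functional_network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tr <- data.frame(module = rep(seq_along(ds$truth),
                                vapply(ds$truth, length, 0L)),
                   gene = unlist(ds$truth), stringsAsFactors = FALSE)
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
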