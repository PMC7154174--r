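# Markov clustering (MCL) of the weighted PPI graph. Flow is simulated
# on a column-stochastic transition matrix by alternating expansion
# (matrix squaring) and inflation (entrywise powering + column
# renormalization) until the flow concentrates into attractors; nodes
# drawing on the same attractor system form a cluster.

#' MCL configuration
#'
#' @param inflation inflation exponent `rp` (> 1); larger values give
#'   finer clusters. Default 2, the canonical MCL setting.
#' @param max_iterations iteration cap; default 100.
#' @param convergence_tol maximum absolute entrywise change between
#'   successive iterates that counts as converged; default 1e-6.
#' @param prune_threshold entries below this are zeroed before each
#'   renormalization (numerical hygiene on sparse flow); default 1e-8.
#' @param attractor_eps minimum limit-matrix mass treated as nonzero when
#'   extracting clusters; default 1e-6.
#' @return an `mcl_config` list.
#' @export
mcl_config <- function(inflation = 2, max_iterations = 100L,
                       convergence_tol = 1e-6, prune_threshold = 1e-8,
                       attractor_eps = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (convergence_tol <= 0 || prune_threshold < 0)
    stop("tolerances must be positive")
  structure(list(inflation = inflation,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 prune_threshold = prune_threshold,
                 attractor_eps = attractor_eps),
            class = "mcl_config")
}

#' Initialize the MCL transition matrix
#'
#' Off-diagonal entries carry the edge weights `ws`; each diagonal entry
#' is a self-loop equal to the node's maximum incident edge weight
#' (1 for isolated nodes), which guarantees positive column sums.
#'
#' @param g weighted undirected igraph (from [build_weighted_graph()]).
#' @return dense square matrix with node names as dimnames.
#' @export
mcl_init_matrix <- function(g) {
  n <- igraph::vcount(g)
  if (n < 1L) stop("graph is empty")
  P <- if (igraph::ecount(g) > 0)
    igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  else
    matrix(0, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  selfw <- apply(P, 1L, max)
  selfw[selfw <= 0] <- 1
  diag(P) <- selfw
  P
}

#' Column-normalize a transition matrix
#'
#' @param P non-negative square matrix with positive column sums.
#' @return column-stochastic matrix.
#' @export
mcl_normalize <- function(P) {
  cs <- colSums(P)
  if (any(cs <= 0)) stop("zero column sum; self-loops missing?")
  sweep(P, 2L, cs, "/")
}

#' MCL expansion step
#'
#' Squares the column-stochastic matrix (`P %*% P`), spreading flow along
#' length-2 walks.
#'
#' @param P column-stochastic matrix.
#' @return column-stochastic matrix.
#' @export
mcl_expand <- function(P) {
  P %*% P
}

#' MCL inflation step
#'
#' Raises every entry to the power `inflation`, zeroes entries below
#' `prune`, and renormalizes columns, amplifying strong flows at the
#' expense of weak ones.
#'
#' @param P column-stochastic matrix.
#' @param inflation exponent > 1.
#' @param prune entries below this are zeroed before renormalization.
#' @return column-stochastic matrix.
#' @export
mcl_inflate <- function(P, inflation, prune = 0) {
  Q <- P^inflation
  if (prune > 0) Q[Q < prune] <- 0
  mcl_normalize(Q)
}

# Cluster extraction from the limit matrix: attractor rows (nonzero
# diagonal mass) that draw flow from a common column belong to one
# attractor system; every column joins the system holding its largest
# entry, ties toward the smallest gene id.
.mcl_extract <- function(P, eps) {
  n <- ncol(P)
  nodes <- colnames(P)
  attr_rows <- which(diag(P) >= eps)
  if (!length(attr_rows)) attr_rows <- sort(unique(max.col(t(P), "first")))

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  for (j in seq_len(n)) {
    rows <- attr_rows[P[attr_rows, j] >= eps]
    if (length(rows) > 1L)
      for (k in rows[-1L]) union2(rows[1L], k)
  }

  assign_to <- integer(n)
  for (j in seq_len(n)) {
    rows <- attr_rows[P[attr_rows, j] >= eps]
    if (!length(rows)) {
      # no attractor mass (non-converged run): fall back to the argmax row
      ent <- P[, j]
      rows <- which(ent == max(ent))
      rows <- rows[order(nodes[rows])][1L]
      if (!(rows %in% attr_rows)) {
        attr_rows <- sort(c(attr_rows, rows))
      }
      assign_to[j] <- find(rows)
    } else {
      ent <- P[rows, j]
      best <- rows[ent == max(ent)]
      best <- best[order(nodes[best])][1L]
      assign_to[j] <- find(best)
    }
  }
  # re-canonicalize after any late unions
  assign_to <- vapply(assign_to, find, 0L)
  cl <- split(nodes, assign_to)
  cl <- lapply(unname(cl), sort)
  cl[order(-vapply(cl, length, 0L), vapply(cl, `[`, "", 1L))]
}

#' Run Markov clustering on a weighted graph
#'
#' Alternates [mcl_expand()] and [mcl_inflate()] from the normalized
#' initial matrix until the maximum absolute entrywise change drops
#' below `convergence_tol` (or `max_iterations` is hit, flagged with a
#' warning), then extracts clusters from the limit matrix. Clusters
#' always partition the node set and never span disconnected components.
#'
#' @param g weighted undirected igraph.
#' @param cfg an [mcl_config()].
#' @return an `mcl_clustering` list: `clusters` (list of sorted gene-id
#'   vectors), `converged`, `iterations`, and `max_colsum_dev` (largest
#'   deviation of any column sum from 1 observed across iterations).
#' @export
run_mcl <- function(g, cfg = mcl_config()) {
  P <- mcl_normalize(mcl_init_matrix(g))
  converged <- FALSE
  it <- 0L
  colsum_dev <- max(abs(colSums(P) - 1))
  while (it < cfg$max_iterations) {
    it <- it + 1L
    Q <- mcl_inflate(mcl_expand(P), cfg$inflation, cfg$prune_threshold)
    colsum_dev <- max(colsum_dev, abs(colSums(Q) - 1))
    delta <- max(abs(Q - P))
    P <- Q
    if (delta < cfg$convergence_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", cfg$max_iterations, " iterations")
  structure(list(clusters = .mcl_extract(P, cfg$attractor_eps),
                 converged = converged, iterations = it,
                 max_colsum_dev = colsum_dev),
            class = "mcl_clustering")
}

#' @exportS3Method base::print
print.mcl_clustering <- function(x, ...) {
  cat("MCL clustering:", length(x$clusters), "cluster(s) in", x$iterations,
      "iteration(s);", if (x$converged) "converged" else "NOT converged", "\n")
  invisible(x)
}
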