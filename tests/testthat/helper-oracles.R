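# Independent oracles and small fixture builders used across the suite.

# per-sample counting oracle for coverage / overlap / exclusivity,
# written as an explicit loop so it shares no code with the package
oracle_mutex <- function(M, genes) {
  n_cov <- 0L
  n_ov <- 0L
  for (s in seq_len(nrow(M))) {
    k <- 0L
    for (g in genes) if (M[s, g] == 1L) k <- k + 1L
    if (k >= 1L) n_cov <- n_cov + 1L
    if (k >= 2L) n_ov <- n_ov + 1L
  }
  list(coverage = n_cov / nrow(M), overlap = n_ov / nrow(M),
       me = n_cov / nrow(M) - n_ov / nrow(M))
}

# brute-force BMA oracle working directly off the raw functional edge
# list (its own min-max normalization and double loop)
oracle_bma <- function(nf, ppi, gi, gj) {
  el <- igraph::as_edgelist(nf)
  ls <- igraph::E(nf)$ls
  rng <- range(ls)
  lsn <- if (rng[1] == rng[2]) rep(1, length(ls)) else
    (ls - rng[1]) / (rng[2] - rng[1])
  pair_sim <- function(a, b) {
    if (a == b) return(1)
    hit <- (el[, 1] == a & el[, 2] == b) | (el[, 1] == b & el[, 2] == a)
    if (any(hit)) lsn[which(hit)[1]] else 0
  }
  set_sim <- function(g, G) {
    best <- 0
    for (h in G) best <- max(best, pair_sim(g, h))
    best
  }
  Gi <- setdiff(names(igraph::neighbors(ppi, gi)), gi)
  Gj <- setdiff(names(igraph::neighbors(ppi, gj)), gj)
  if (!length(Gi) || !length(Gj)) return(0)
  tot <- 0
  for (g in Gi) tot <- tot + set_sim(g, Gj)
  for (g in Gj) tot <- tot + set_sim(g, Gi)
  tot / (length(Gi) + length(Gj))
}

# exact null distribution of pairwise ME under gene-wise column
# permutation, by enumerating all placements of both columns
oracle_null_pvalue <- function(n, m1, m2, obs) {
  c1 <- utils::combn(n, m1)
  c2 <- utils::combn(n, m2)
  exceed <- 0L
  total <- 0L
  for (i in seq_len(ncol(c1))) {
    for (j in seq_len(ncol(c2))) {
      counts <- tabulate(c(c1[, i], c2[, j]), nbins = n)
      me <- sum(counts == 1L) / n
      total <- total + 1L
      if (me >= obs - 1e-9) exceed <- exceed + 1L
    }
  }
  exceed / total
}

# random binary mutation matrix with labelled dims
random_mutation_matrix <- function(n, p, rate = 0.3) {
  M <- matrix(rbinom(n * p, 1L, rate), n, p,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              sprintf("g%02d", seq_len(p))))
  storage.mode(M) <- "integer"
  M
}

# small mutation matrix from explicit sample lists per gene
matrix_from_events <- function(samples, events) {
  genes <- names(events)
  M <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  for (g in genes) M[events[[g]], g] <- 1L
  M
}

# random toy PPI + functional network pair over a shared gene universe
random_toy_networks <- function(n_genes = 8, p_edge = 0.4) {
  genes <- sprintf("t%02d", seq_len(n_genes))
  cmb <- utils::combn(genes, 2)
  pick <- runif(ncol(cmb)) < p_edge
  if (sum(pick) < 2) pick[1:2] <- TRUE
  ppi <- igraph::graph_from_data_frame(
    data.frame(from = cmb[1, pick], to = cmb[2, pick]),
    directed = FALSE, vertices = data.frame(name = genes))
  pick2 <- runif(ncol(cmb)) < p_edge
  if (sum(pick2) < 2) pick2[1:2] <- TRUE
  nf <- igraph::graph_from_data_frame(
    data.frame(from = cmb[1, pick2], to = cmb[2, pick2],
               ls = runif(sum(pick2), 0, 5)),
    directed = FALSE, vertices = data.frame(name = genes))
  list(ppi = ppi, nf = nf, genes = genes)
}

# weighted toy graph builder for MCL tests
weighted_graph <- function(edges, weights, vertices = NULL) {
  df <- data.frame(from = edges[, 1], to = edges[, 2], weight = weights,
                   stringsAsFactors = FALSE)
  if (is.null(vertices))
    vertices <- data.frame(name = sort(unique(c(df$from, df$to))))
  igraph::graph_from_data_frame(df, directed = FALSE, vertices = vertices)
}
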