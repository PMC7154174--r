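toy_nf <- function(edges_ls) {
  df <- data.frame(from = edges_ls[[1]], to = edges_ls[[2]],
                   ls = edges_ls[[3]], stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE)
}

test_that("min-max normalization maps the LS range onto [0, 1]", {
  nf <- toy_nf(list(c("A", "B", "C"), c("B", "C", "D"), c(1, 3, 5)))
  nfn <- normalize_ls(nf)
  expect_equal(gene_similarity(nfn, "A", "B"), 0)
  expect_equal(gene_similarity(nfn, "B", "C"), 0.5)
  expect_equal(gene_similarity(nfn, "C", "D"), 1)
})

test_that("degenerate LS range falls back to LS_N = 1 with a warning", {
  nf <- toy_nf(list(c("A", "B"), c("B", "C"), c(2, 2)))
  expect_warning(nfn <- normalize_ls(nf), "degenerate")
  expect_equal(gene_similarity(nfn, "A", "B"), 1)
})

test_that("pairwise gene similarity follows the three-case definition", {
  nf <- toy_nf(list(c("A", "B"), c("B", "C"), c(1, 5)))
  nfn <- normalize_ls(nf)
  expect_equal(gene_similarity(nfn, "A", "A"), 1)
  expect_equal(gene_similarity(nfn, "A", "C"), 0)      # no edge
  expect_equal(gene_similarity(nfn, "A", "unknown"), 0)
  expect_equal(gene_similarity(nfn, "A", "B"), 0)      # edge at LS_min
  expect_equal(gene_similarity(nfn, "B", "C"), 1)      # edge at LS_max
})

test_that("gene-to-set similarity is the best match", {
  nf <- toy_nf(list(c("A", "A", "A"), c("B", "C", "D"), c(0, 3, 7)))
  nfn <- normalize_ls(nf)
  expect_equal(gene_set_similarity(nfn, "A", c("B", "C", "D")), 1) # LS_max edge
  expect_equal(gene_set_similarity(nfn, "A", c("B", "C")), 3 / 7)
  expect_equal(gene_set_similarity(nfn, "A", c("A", "B")), 1)      # member
  expect_equal(gene_set_similarity(nfn, "Z", c("B", "C")), 0)      # disconnected
  expect_error(gene_set_similarity(nfn, "A", character(0)), "non-empty")
})

test_that("BMA similarity is 1 for identical neighborhoods and 0 when isolated", {
  # star: A and B both neighbor exactly {C, D}
  ppi <- weighted_graph(cbind(c("A", "A", "B", "B"), c("C", "D", "C", "D")),
                        rep(1, 4),
                        vertices = data.frame(name = c("A", "B", "C", "D", "E")))
  nf <- toy_nf(list(c("C", "A"), c("D", "B"), c(1, 2)))
  nfn <- normalize_ls(nf)
  expect_equal(bma_similarity(nfn, ppi, "A", "B"), 1)
  expect_warning(s <- bma_similarity(nfn, ppi, "A", "E"), "no PPI neighbors")
  expect_equal(s, 0)
})

test_that("BMA matches a hand-computed five-node example", {
  # PPI: A-B, A-C, B-D, B-E  =>  G_A = {B, C}, G_B = {A, D, E}
  ppi <- weighted_graph(cbind(c("A", "A", "B", "B"), c("B", "C", "D", "E")),
                        rep(1, 4))
  # NF scores (min 0, max 4): B-C: 2 -> 0.5, C-D: 4 -> 1, A-C: 0 -> 0, D-E: 3 -> 0.75
  nf <- toy_nf(list(c("B", "C", "A", "D"), c("C", "D", "C", "E"), c(2, 4, 0, 3)))
  nfn <- normalize_ls(nf)
  # S(B, G_B): B vs {A, D, E} -> 0; S(C, G_B): C vs {A, D, E} -> max(0, 1, 0) = 1
  # S(A, G_A): A vs {B, C} -> max(0, 0) = 0
  # S(D, G_A): D vs {B, C} -> max(0, 1) = 1
  # S(E, G_A): E vs {B, C} -> 0
  expect_equal(bma_similarity(nfn, ppi, "A", "B"), (0 + 1 + 0 + 1 + 0) / 5)
  expect_equal(bma_similarity(nfn, ppi, "A", "B"),
               oracle_bma(nf, ppi, "A", "B"))
})

test_that("BMA is symmetric, bounded and matches the brute-force oracle", {
  set.seed(31)
  for (rep in 1:25) {
    tn <- random_toy_networks()
    nfn <- normalize_ls(tn$nf)
    pair <- sample(tn$genes, 2)
    deg <- igraph::degree(tn$ppi)[pair]
    if (any(deg == 0)) next
    s_ij <- bma_similarity(nfn, tn$ppi, pair[1], pair[2])
    s_ji <- bma_similarity(nfn, tn$ppi, pair[2], pair[1])
    expect_equal(s_ij, s_ji)
    expect_gte(s_ij, 0)
    expect_lte(s_ij, 1)
    expect_equal(s_ij, oracle_bma(tn$nf, tn$ppi, pair[1], pair[2]),
                 tolerance = 1e-12)
  }
})

test_that("adding a functional edge never decreases BMA similarity", {
  set.seed(32)
  tn <- random_toy_networks(n_genes = 6, p_edge = 0.6)
  nfn <- normalize_ls(tn$nf)
  rng <- nfn$ls_range
  # add a fresh NF edge with an in-range score (normalization unchanged)
  all_pairs <- t(utils::combn(tn$genes, 2))
  existing <- igraph::as_edgelist(tn$nf)
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  free <- all_pairs[!(key(all_pairs) %in% key(existing)), , drop = FALSE]
  expect_gt(nrow(free), 0)
  nf2 <- igraph::add_edges(tn$nf, free[1, ], attr = list(ls = mean(rng)))
  nfn2 <- normalize_ls(nf2)
  deg <- igraph::degree(tn$ppi)
  for (i in 1:10) {
    pair <- sample(tn$genes[deg > 0], 2)
    expect_gte(bma_similarity(nfn2, tn$ppi, pair[1], pair[2]),
               bma_similarity(nfn, tn$ppi, pair[1], pair[2]) - 1e-12)
  }
})
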