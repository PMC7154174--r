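test_that("all-zero gene columns give ME 0 and p = 1", {
  M <- matrix(0L, 6, 2, dimnames = list(sprintf("s%d", 1:6), c("A", "B")))
  res <- permutation_test(M, c("A", "B"),
                          permutation_config(n_permutations = 99, seed = 1))
  expect_equal(res$observed_me, 0)
  expect_equal(res$p_value, 1)
})

test_that("a perfectly exclusive covering pair attains the minimum p", {
  M <- matrix_from_events(sprintf("s%02d", 1:20),
                          list(A = sprintf("s%02d", 1:10),
                               B = sprintf("s%02d", 11:20)))
  cfg <- permutation_config(n_permutations = 200, seed = 2)
  res <- permutation_test(M, c("A", "B"), cfg)
  expect_equal(res$observed_me, 1)
  expect_equal(res$p_value, 1 / 201)
  expect_identical(res$exceedances, 0L)
})

test_that("Monte-Carlo p matches the exhaustively enumerated null on a toy", {
  M <- matrix_from_events(sprintf("s%d", 1:6),
                          list(A = c("s1", "s2"), B = c("s3", "s4", "s5")))
  obs <- mutex_score(M, c("A", "B"))$me
  exact <- oracle_null_pvalue(6, 2, 3, obs)
  cfg <- permutation_config(n_permutations = 4000, seed = 3,
                            early_stop = FALSE)
  res <- permutation_test(M, c("A", "B"), cfg)
  expect_lt(abs(res$p_value - exact), 0.03)
})

test_that("p-values are seed-reproducible and row-order invariant", {
  set.seed(61)
  M <- random_mutation_matrix(30, 6, rate = 0.25)
  cfg <- permutation_config(n_permutations = 200, seed = 7)
  r1 <- permutation_test(M, c("g01", "g02", "g03"), cfg)
  r2 <- permutation_test(M, c("g01", "g02", "g03"), cfg)
  expect_identical(r1, r2)
  perm <- sample(nrow(M))
  r3 <- permutation_test(M[perm, , drop = FALSE], c("g01", "g02", "g03"), cfg)
  expect_identical(r3$p_value, r1$p_value)
})

test_that("the switching null preserves both margins and is reproducible", {
  M <- matrix_from_events(sprintf("s%02d", 1:12),
                          list(A = sprintf("s%02d", 1:6),
                               B = sprintf("s%02d", 7:12),
                               C = sprintf("s%02d", c(1, 7, 9))))
  cfg <- permutation_config(n_permutations = 100, seed = 8,
                            null_model = "switching")
  r1 <- permutation_test(M, c("A", "B", "C"), cfg)
  r2 <- permutation_test(M, c("A", "B", "C"), cfg)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 101)
  expect_lte(r1$p_value, 1)
})

test_that("a significant cluster is retained whole", {
  M <- matrix_from_events(sprintf("s%02d", 1:12),
                          list(A = sprintf("s%02d", 1:4),
                               B = sprintf("s%02d", 5:8),
                               C = sprintf("s%02d", 9:12)))
  rec <- refine_cluster(M, c("A", "B", "C"),
                        permutation_config(n_permutations = 200, seed = 9))
  expect_identical(rec$genes, c("A", "B", "C"))
  expect_equal(rec$me, 1)
  expect_lt(rec$p_value, 0.05)
})

test_that("descent recovers the exclusive 3-subset of a diluted 4-cluster", {
  # A, B, C perfectly exclusive over 15 of 16 samples; D mutated
  # everywhere, overlapping every other gene
  M <- matrix_from_events(sprintf("s%02d", 1:16),
                          list(A = sprintf("s%02d", 1:5),
                               B = sprintf("s%02d", 6:10),
                               C = sprintf("s%02d", 11:15),
                               D = sprintf("s%02d", 1:16)))
  cfg <- permutation_config(n_permutations = 400, seed = 10)
  expect_gt(permutation_test(M, c("A", "B", "C", "D"), cfg)$p_value, 0.05)
  rec <- refine_cluster(M, c("A", "B", "C", "D"), cfg)
  expect_identical(rec$genes, c("A", "B", "C"))
  expect_lt(rec$p_value, 0.05)
})

test_that("random co-mutated clusters are rejected entirely", {
  # five genes mutated in exactly the same samples: ME is 0
  M <- matrix_from_events(sprintf("s%02d", 1:10),
                          as.list(setNames(rep(list(sprintf("s%02d", 1:5)), 5),
                                           paste0("G", 1:5))))
  rec <- refine_cluster(M, paste0("G", 1:5),
                        permutation_config(n_permutations = 100, seed = 11))
  expect_null(rec)
})

test_that("refine_all filters small clusters, sorts, and annotates ws", {
  M <- matrix_from_events(sprintf("s%02d", 1:12),
                          list(A = sprintf("s%02d", 1:4),
                               B = sprintf("s%02d", 5:8),
                               C = sprintf("s%02d", 9:12),
                               D = sprintf("s%02d", c(1, 5)),
                               E = sprintf("s%02d", c(1, 5))))
  wg <- weighted_graph(cbind(c("A", "B", "C"), c("B", "C", "A")),
                       c(0.5, 0.7, 0.9))
  cfg <- permutation_config(n_permutations = 200, seed = 12)
  mods <- refine_all(M, list(c("A", "B", "C"), c("D", "E")), cfg, wgraph = wg)
  expect_s3_class(mods, "driver_modules")
  expect_length(mods, 1L)
  expect_identical(mods[[1]]$genes, c("A", "B", "C"))
  expect_equal(mods[[1]]$mean_ws, mean(c(0.5, 0.7, 0.9)))

  expect_length(refine_all(M, list(), cfg), 0L)
  expect_length(refine_all(M, list(c("A", "B"), c("D", "E")), cfg), 0L)
})

test_that("refinement is bit-reproducible under a fixed seed", {
  set.seed(62)
  M <- random_mutation_matrix(40, 8, rate = 0.15)
  cfg <- permutation_config(n_permutations = 100, seed = 13)
  cl <- list(colnames(M)[1:5], colnames(M)[5:8])
  expect_identical(refine_all(M, cl, cfg), refine_all(M, cl, cfg))
})

test_that("greedy descent engages above the exhaustive cap", {
  M <- matrix_from_events(sprintf("s%02d", 1:12),
                          list(A = sprintf("s%02d", 1:4),
                               B = sprintf("s%02d", 5:8),
                               C = sprintf("s%02d", 9:12),
                               D = sprintf("s%02d", 1:12)))
  cfg <- permutation_config(n_permutations = 200, seed = 14)
  rec <- refine_cluster(M, c("A", "B", "C", "D"), cfg, max_exhaustive = 3L)
  expect_true(rec$greedy)
  expect_identical(rec$genes, c("A", "B", "C"))
})
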