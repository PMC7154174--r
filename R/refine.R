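# Module refinement: a permutation test decides whether a cluster's
# group exclusivity exceeds chance; non-significant clusters are
# recursively decomposed into subgroups (down to size 3) and the most
# significant subgroup, if any, is kept as the driver module.

#' Permutation-test configuration
#'
#' @param n_permutations number of null draws; default 1000.
#' @param alpha significance level for module retention; default 0.05.
#' @param seed optional integer seed; when set, results are
#'   bit-reproducible and the caller's RNG state is left untouched.
#' @param null_model `"gene-wise"` (default; permutes each gene's column
#'   independently across samples, preserving per-gene mutation
#'   frequency) or `"switching"` (checkerboard 0/1 swaps preserving both
#'   sample and gene mutation counts of the tested submatrix).
#' @param early_stop if `TRUE` (default), testing stops early once the
#'   exceedance count guarantees that the full-run p-value could not fall
#'   below `alpha`. Significance calls are unchanged; clearly
#'   non-significant sets just cost fewer draws.
#' @return a `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 1000L, alpha = 0.05,
                               seed = NULL,
                               null_model = c("gene-wise", "switching"),
                               early_stop = TRUE) {
  n_permutations <- as.integer(n_permutations)
  if (is.na(n_permutations) || n_permutations < 1L)
    stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(n_permutations = n_permutations, alpha = alpha,
                 seed = seed, null_model = match.arg(null_model),
                 early_stop = isTRUE(early_stop)),
            class = "permutation_config")
}

.with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# one chain step block for the switching null: attempted checkerboard
# swaps on the 1-cells, preserving row and column sums
.swap_step <- function(sub, ones, attempts) {
  m <- nrow(ones)
  if (m >= 2L) {
    for (t in seq_len(attempts)) {
      pick <- sample.int(m, 2L)
      r1 <- ones[pick[1L], 1L]; c1 <- ones[pick[1L], 2L]
      r2 <- ones[pick[2L], 1L]; c2 <- ones[pick[2L], 2L]
      if (r1 != r2 && c1 != c2 && sub[r1, c2] == 0L && sub[r2, c1] == 0L) {
        sub[r1, c1] <- 0L; sub[r2, c2] <- 0L
        sub[r1, c2] <- 1L; sub[r2, c1] <- 1L
        ones[pick[1L], 2L] <- c2; ones[pick[2L], 2L] <- c1
      }
    }
  }
  list(sub = sub, ones = ones)
}

#' Permutation test for group mutual exclusivity
#'
#' Compares the observed `ME` of a gene set with its null distribution
#' under random rewiring of the mutation matrix and reports the add-one
#' estimator `p = (1 + #\{null ME >= observed\}) / (1 + n)`, which never
#' returns exactly zero; the raw exceedance count is reported alongside.
#'
#' @param M binary mutation matrix.
#' @param genes gene set of size >= 2.
#' @param cfg a [permutation_config()].
#' @return a `mutex_perm_test` list: `p_value`, `exceedances`, `n_used`
#'   (null draws actually performed), `observed_me`, `null_model`.
#' @export
permutation_test <- function(M, genes, cfg = permutation_config()) {
  .check_genes(M, genes)
  if (length(genes) < 2L) stop("permutation test needs at least 2 genes")
  .with_local_seed(cfg$seed, {
    n <- nrow(M)
    obs <- mutex_score(M, genes)$me
    B <- cfg$n_permutations
    # exceedances at which even a full run could not reach p < alpha
    stop_exc <- if (cfg$early_stop) ceiling(cfg$alpha * (B + 1) - 1) else Inf
    exc <- 0L
    done <- 0L
    batch <- 50L
    if (cfg$null_model == "gene-wise") {
      m <- as.integer(colSums(M[, genes, drop = FALSE]))
      res <- .null_exceedances(n, m, B, obs,
                               if (is.finite(stop_exc))
                                 as.integer(stop_exc) else B + 1L)
      exc <- res[1L]
      done <- res[2L]
    } else {
      sub <- M[, genes, drop = FALSE]
      ones <- which(sub == 1L, arr.ind = TRUE)
      dimnames(ones) <- NULL
      attempts <- max(2L * nrow(ones), 100L)
      while (done < B) {
        nb <- min(batch, B - done)
        for (b in seq_len(nb)) {
          st <- .swap_step(sub, ones, attempts)
          sub <- st$sub; ones <- st$ones
          counts <- tabulate(ones[, 1L], nbins = n)
          if (sum(counts == 1L) / n >= obs - 1e-9) exc <- exc + 1L
        }
        done <- done + nb
        if (exc >= stop_exc) break
      }
    }
    structure(list(p_value = (1 + exc) / (1 + done), exceedances = exc,
                   n_used = done, observed_me = obs,
                   null_model = cfg$null_model),
              class = "mutex_perm_test")
  })
}

# ordering used to pick "the most significant" subgroup:
# smaller p, then larger ME, then larger size, then lexicographic genes
.module_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$p_value != b$p_value) return(a$p_value < b$p_value)
  if (a$me != b$me) return(a$me > b$me)
  if (length(a$genes) != length(b$genes))
    return(length(a$genes) > length(b$genes))
  paste(a$genes, collapse = ";") < paste(b$genes, collapse = ";")
}

.module_record <- function(genes, test, greedy = FALSE) {
  list(genes = genes, size = length(genes), me = test$observed_me,
       p_value = test$p_value, exceedances = test$exceedances,
       n_permutations = test$n_used, mean_ws = NA_real_, greedy = greedy)
}

#' Refine one candidate cluster into a driver module
#'
#' If the whole cluster is significantly exclusive (`p < alpha`) it is
#' returned as-is. Otherwise every subgroup of one fewer gene is tested
#' and the descent recurses into non-significant subgroups, stopping at
#' `min_module_size`; among all significant subgroups encountered, the
#' one with the smallest p-value is returned (ties broken by larger ME,
#' then larger size, then lexicographic gene order). `NULL` if no
#' subgroup of size >= `min_module_size` is significant. Tested subgroups
#' are memoized, and clusters larger than `max_exhaustive` fall back to a
#' greedy descent that repeatedly removes the gene whose removal
#' maximizes ME (the result is flagged `greedy = TRUE`).
#'
#' @param M binary mutation matrix.
#' @param cluster gene set from MCL (clusters smaller than
#'   `min_module_size` are rejected upstream and return `NULL` here).
#' @param cfg a [permutation_config()].
#' @param min_module_size smallest admissible module; default 3.
#' @param max_exhaustive largest cluster size descended exhaustively;
#'   default 12.
#' @return a module record (list with `genes`, `size`, `me`, `p_value`,
#'   `exceedances`, `n_permutations`, `mean_ws`, `greedy`) or `NULL`.
#' @export
refine_cluster <- function(M, cluster, cfg = permutation_config(),
                           min_module_size = 3L, max_exhaustive = 12L) {
  cluster <- sort(unique(as.character(cluster)))
  if (length(cluster) < min_module_size) return(NULL)
  .with_local_seed(cfg$seed, {
    icfg <- cfg
    icfg$seed <- NULL
    memo <- new.env(parent = emptyenv())
    test_set <- function(gs) {
      key <- paste(gs, collapse = ";")
      res <- memo[[key]]
      if (is.null(res)) {
        res <- permutation_test(M, gs, icfg)
        memo[[key]] <- res
      }
      res
    }
    best <- NULL
    consider <- function(rec) if (.module_better(rec, best)) best <<- rec

    if (length(cluster) > max_exhaustive) {
      gs <- cluster
      repeat {
        res <- test_set(gs)
        if (res$p_value < cfg$alpha) {
          consider(.module_record(gs, res, greedy = TRUE))
          break
        }
        if (length(gs) <= min_module_size) break
        mes <- vapply(seq_along(gs),
                      function(i) mutex_score(M, gs[-i])$me, numeric(1L))
        gs <- gs[-which.max(mes)]
      }
    } else {
      visited <- new.env(parent = emptyenv())
      recurse <- function(gs) {
        key <- paste(gs, collapse = ";")
        if (!is.null(visited[[key]])) return(invisible(NULL))
        visited[[key]] <- TRUE
        res <- test_set(gs)
        if (res$p_value < cfg$alpha) {
          consider(.module_record(gs, res))
          return(invisible(NULL))
        }
        if (length(gs) > min_module_size)
          for (i in seq_along(gs)) recurse(gs[-i])
        invisible(NULL)
      }
      recurse(cluster)
    }
    best
  })
}

#' Refine every MCL cluster into driver modules
#'
#' Applies [refine_cluster()] to each cluster of size >=
#' `min_module_size` (processed in a deterministic order) and annotates
#' retained modules with their mean internal edge weight `mean_ws`
#' (average `ws` over the weighted-graph edges inside the module; 0 if
#' none). Results are sorted by ascending p-value, ties by descending
#' `mean_ws`.
#'
#' @param M binary mutation matrix.
#' @param clustering an `mcl_clustering` from [run_mcl()] or a plain list
#'   of gene-id vectors.
#' @param cfg a [permutation_config()].
#' @param wgraph optional weighted graph from [build_weighted_graph()]
#'   used to compute `mean_ws`.
#' @inheritParams refine_cluster
#' @return a `driver_modules` list of module records.
#' @export
refine_all <- function(M, clustering, cfg = permutation_config(),
                       wgraph = NULL, min_module_size = 3L,
                       max_exhaustive = 12L) {
  clusters <- if (inherits(clustering, "mcl_clustering"))
    clustering$clusters else clustering
  clusters <- lapply(clusters, function(cl) sort(unique(as.character(cl))))
  clusters <- clusters[vapply(clusters, length, 0L) >= min_module_size]
  if (length(clusters)) {
    ord <- order(vapply(clusters, `[`, "", 1L),
                 -vapply(clusters, length, 0L))
    clusters <- clusters[ord]
  }
  .with_local_seed(cfg$seed, {
    icfg <- cfg
    icfg$seed <- NULL
    mods <- list()
    for (cl in clusters) {
      rec <- refine_cluster(M, cl, icfg, min_module_size, max_exhaustive)
      if (!is.null(rec)) {
        rec$mean_ws <- .mean_internal_ws(wgraph, rec$genes)
        mods[[length(mods) + 1L]] <- rec
      }
    }
    if (length(mods)) {
      p <- vapply(mods, function(m) m$p_value, 0)
      w <- vapply(mods, function(m) if (is.na(m$mean_ws)) 0 else m$mean_ws, 0)
      mods <- mods[order(p, -w)]
    }
    structure(mods, class = "driver_modules")
  })
}

.mean_internal_ws <- function(wgraph, genes) {
  if (is.null(wgraph)) return(NA_real_)
  keep <- intersect(genes, igraph::V(wgraph)$name)
  if (length(keep) < 2L) return(0)
  sub <- igraph::induced_subgraph(wgraph, keep)
  w <- igraph::E(sub)$weight
  if (!length(w)) 0 else mean(w)
}
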