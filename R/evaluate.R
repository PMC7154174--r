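# Recovery scoring against the planted truth (gene-level precision,
# recall, F1) and the benchmark harness sweeping noise and passenger
# rates through the full pipeline.

#' Gene-level F1 score of predicted modules
#'
#' Scores the union of predicted gene sets against the union of planted
#' sets: `TP` genes in both, `FP` predicted only, `FN` planted only;
#' `Pr = TP/(TP+FP)`, `Re = TP/(TP+FN)`,
#' `F1 = 2*Pr*Re/(Pr+Re)` (0 when `Pr + Re = 0`).
#'
#' @param predicted list of predicted gene sets (character vectors); an
#'   empty list scores 0.
#' @param truth non-empty list of planted gene sets.
#' @return a `benchmark_score` list: `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn`.
#' @export
f1_score <- function(predicted, truth) {
  if (!length(truth)) stop("truth must be non-empty")
  pu <- unique(unlist(predicted))
  tu <- unique(unlist(truth))
  tp <- length(intersect(pu, tu))
  fp <- length(setdiff(pu, tu))
  fn <- length(setdiff(tu, pu))
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + re > 0) 2 * pr * re / (pr + re) else 0
  structure(list(precision = pr, recall = re, f1 = f1,
                 tp = tp, fp = fp, fn = fn),
            class = "benchmark_score")
}

#' Select the top-ranked modules
#'
#' Orders modules by ascending p-value, ties by descending mean internal
#' edge weight (`mean_ws`), and keeps the first `k` — so for `k = 1` the
#' module with the lowest p-value and, among those, the highest `ws` is
#' selected.
#'
#' @param modules `driver_modules` list from [refine_all()].
#' @param k number of modules to keep; default 1.
#' @return list of up to `k` gene sets (character vectors).
#' @export
select_top_modules <- function(modules, k = 1L) {
  if (!length(modules)) return(list())
  p <- vapply(modules, function(m) m$p_value, 0)
  w <- vapply(modules, function(m) if (is.na(m$mean_ws)) 0 else m$mean_ws, 0)
  ord <- order(p, -w)
  lapply(modules[ord[seq_len(min(k, length(modules)))]],
         function(m) m$genes)
}

#' Benchmark module recovery over a noise / passenger-rate grid
#'
#' For every combination of `noise_grid` and `passenger_grid`, generates
#' `n_replicates` simulated datasets ([generate_dataset()]), runs the
#' full pipeline ([find_driver_modules()]), selects the top `n_modules`
#' results and scores them against the planted truth with [f1_score()].
#' Deterministic given `seed` (per-replicate seeds are derived from it).
#'
#' @param noise_grid numeric vector of flip-noise levels.
#' @param passenger_grid numeric vector of passenger mutation rates.
#' @param n_modules number of planted (and selected) modules; default 1.
#' @param n_replicates replicates per grid cell; default 20.
#' @param seed integer master seed; default 1.
#' @param n_samples,n_genes,module_sizes,module_coverage forwarded to
#'   [sim_config()].
#' @param perm_cfg a [permutation_config()] template (its seed field is
#'   overridden per replicate).
#' @param mcl_cfg an [mcl_config()].
#' @return data.frame with one row per replicate: grid coordinates,
#'   `replicate`, `seed`, `precision`, `recall`, `f1`.
#' @export
run_benchmark <- function(noise_grid, passenger_grid, n_modules = 1L,
                          n_replicates = 20L, seed = 1L,
                          n_samples = 500L, n_genes = 200L,
                          module_sizes = rep(4L, n_modules),
                          module_coverage = 0.9,
                          perm_cfg = permutation_config(),
                          mcl_cfg = mcl_config()) {
  if (!length(noise_grid) || !length(passenger_grid))
    stop("grids must be non-empty")
  rows <- list()
  idx <- 0L
  for (noise in noise_grid) {
    for (pr in passenger_grid) {
      for (r in seq_len(n_replicates)) {
        idx <- idx + 1L
        rep_seed <- (as.integer(seed) %% 100000L) * 10007L + idx * 7919L
        rep_seed <- rep_seed %% 2147483647L
        cfg <- sim_config(n_samples = n_samples, n_genes = n_genes,
                          n_modules = n_modules,
                          module_sizes = module_sizes,
                          module_coverage = module_coverage,
                          noise = noise, passenger_rate = pr,
                          seed = rep_seed)
        ds <- generate_dataset(cfg)
        pcfg <- perm_cfg
        pcfg$seed <- (rep_seed + 1L) %% 2147483647L
        mods <- find_driver_modules(ds$M, ds$ppi, ds$nf,
                                    perm_cfg = pcfg, mcl_cfg = mcl_cfg)
        sc <- f1_score(select_top_modules(mods, n_modules), ds$truth)
        rows[[idx]] <- data.frame(noise = noise, passenger_rate = pr,
                                  n_modules = n_modules, replicate = r,
                                  seed = rep_seed,
                                  precision = sc$precision,
                                  recall = sc$recall, f1 = sc$f1)
      }
    }
  }
  do.call(rbind, rows)
}
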