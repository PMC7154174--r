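# CCF-based sharpening of the binary mutation matrix. Larger CCF values
# mark clonal, earlier mutations; the filter keeps those stronger signals
# and discards low-confidence calls before exclusivity is scored.

#' Configuration for the CCF filter
#'
#' @param epsilon minimum CCF gap (in \(0, 1\)) between two mutations of
#'   the same gene for both to survive the near-tie sweep; default 0.1.
#' @param enabled if `FALSE`, [filter_mutations()] returns its input
#'   unchanged.
#' @param min_mut_for_trim minimum number of mutations a gene must have
#'   before its single lowest-CCF mutation is removed (default 2, so a
#'   gene's only mutation is never deleted).
#' @return a `ccf_filter_config` list.
#' @export
ccf_filter_config <- function(epsilon = 0.1, enabled = TRUE,
                              min_mut_for_trim = 2L) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 1)
    stop("epsilon must be a single value in (0, 1)")
  structure(list(epsilon = epsilon, enabled = isTRUE(enabled),
                 min_mut_for_trim = as.integer(min_mut_for_trim)),
            class = "ccf_filter_config")
}

#' Filter a mutation matrix by Cancer Cell Fraction
#'
#' Per gene, two deletion rules are applied to its mutations:
#' \enumerate{
#'   \item if the gene carries at least `min_mut_for_trim` mutations, the
#'     single mutation with the lowest CCF is removed (CCF ties broken
#'     toward the lexicographically smallest sample id);
#'   \item the surviving mutations are scanned in descending CCF order;
#'     whenever the current survivor and the next mutation differ by less
#'     than `epsilon`, the lower one is removed and the scan continues
#'     from the survivor.
#' }
#' Genes left with no mutations are dropped from the gene list. The
#' result never depends on the row order of the input.
#'
#' @param M binary mutation matrix (samples x genes).
#' @param C CCF matrix aligned to `M`; every cell with `M == 1` must hold
#'   a defined CCF in \[0, 1\].
#' @param cfg a [ccf_filter_config()].
#' @return filtered mutation matrix, entrywise `<= M`, possibly with
#'   fewer gene columns.
#' @export
filter_mutations <- function(M, C, cfg = ccf_filter_config()) {
  validate_mutation_matrix(M)
  if (!cfg$enabled) return(M)
  if (!identical(dim(M), dim(C)) ||
      !identical(rownames(M), rownames(C)) ||
      !identical(colnames(M), colnames(C)))
    stop("CCF matrix is not aligned to the mutation matrix")
  miss <- which(M == 1L & is.na(C), arr.ind = TRUE)
  if (nrow(miss)) {
    cells <- paste0("(", rownames(M)[miss[, 1L]], ", ",
                    colnames(M)[miss[, 2L]], ")")
    stop("mutations without a CCF value: ",
         paste(utils::head(cells, 5L), collapse = ", "),
         if (length(cells) > 5L) sprintf(" and %d more", length(cells) - 5L))
  }
  out <- M
  smp_all <- rownames(M)
  for (j in seq_len(ncol(M))) {
    idx <- which(out[, j] == 1L)
    if (!length(idx)) next
    ccfs <- C[idx, j]
    smp <- smp_all[idx]
    keep <- seq_along(idx)
    if (length(idx) >= cfg$min_mut_for_trim) {
      lowest <- order(ccfs, smp)[1L]
      out[idx[lowest], j] <- 0L
      keep <- setdiff(keep, lowest)
    }
    if (length(keep) >= 2L) {
      ord <- keep[order(-ccfs[keep], smp[keep])]
      surv <- ord[1L]
      for (k in ord[-1L]) {
        if (ccfs[surv] - ccfs[k] < cfg$epsilon) {
          out[idx[k], j] <- 0L
        } else {
          surv <- k
        }
      }
    }
  }
  out[, colSums(out) > 0L, drop = FALSE]
}
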