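# Correlation-weighted quantification.
#
# A precursor quantity is the double sum over its top library fragments
#   Q = sum_i sum_j Corr(C_i, C_j) * Area(C_i)
# i.e. each fragment's chromatogram area weighted by the sum of its
# Pearson correlations with all fragments of the same precursor (the
# self-pair i = j, Corr = 1, is included). Areas are trapezoidal
# integrals over the RSM window using per-cycle RT spacing in seconds.
# Protein quantities are the sum of the top-three precursor quantities.

trapezoid_area <- function(values, rt) {
  if (length(values) < 2L) return(0)
  sum((values[-1L] + values[-length(values)]) / 2 * diff(rt))
}

#' Quantify a precursor from its best RSM
#'
#' Uses the first \code{top_n} library rows of the RSM at the basic
#' resolution; these are already sorted by the sum of their Pearson
#' correlations with the other library rows. All-zero rows carry no
#' signal and are skipped.
#'
#' @param rsm The precursor's best-scoring \code{dia_rsm}.
#' @param top_n Number of library fragments used (default six).
#' @return A list with \code{Q} (weighted area), \code{fragments_used},
#'   \code{weights} and \code{areas}.
#' @export
quantify_precursor <- function(rsm, top_n = 6L) {
  blocks <- rsm_blocks(rsm)
  lib <- rsm$matrix[blocks$library_r, , drop = FALSE]
  nz <- which(rowSums(lib != 0) > 0)
  use <- nz[seq_len(min(top_n, length(nz)))]
  if (length(use) == 0L) {
    warning("all library chromatograms are zero; Q = 0")
    return(list(Q = 0, fragments_used = 0L, weights = numeric(),
                areas = numeric()))
  }
  m <- lib[use, , drop = FALSE]
  C <- row_cor_matrix(m)
  diag(C) <- 1  # self-pair always contributes Corr = 1
  weights <- rowSums(C)
  areas <- apply(m, 1L, trapezoid_area, rt = rsm$rt)
  list(Q = sum(weights * areas), fragments_used = length(use),
       weights = weights, areas = areas)
}

#' Add correlation-weighted areas of top self fragments
#'
#' Optional quantification mode: the base quantity is augmented with the
#' top \code{k} self rows (already sorted by their correlation with the
#' first library row), each weighted by that correlation.
#'
#' @param rsm The precursor's best \code{dia_rsm}.
#' @param k Number of self fragments, between 3 and 15.
#' @param top_n Library fragments for the base quantity.
#' @export
quantify_with_self_fragments <- function(rsm, k, top_n = 6L) {
  if (k < 3L || k > 15L) stop("k must be between 3 and 15")
  base <- quantify_precursor(rsm, top_n)
  blocks <- rsm_blocks(rsm)
  if (is.null(blocks$self)) stop("RSM has no self part")
  lib1 <- rsm$matrix[blocks$library_r[1L], ]
  self <- rsm$matrix[blocks$self[seq_len(k)], , drop = FALSE]
  w <- rows_cor_vector(self, lib1)
  areas <- apply(self, 1L, trapezoid_area, rt = rsm$rt)
  base$Q <- base$Q + sum(w * areas)
  base$self_fragments_used <- sum(rowSums(self != 0) > 0)
  base
}

#' Protein quantity: top-three precursor rollup
#'
#' @param q Numeric vector of precursor quantities for one protein.
#' @return Sum of the three largest values (all when fewer).
#' @export
quantify_protein <- function(q) {
  if (length(q) == 0L) stop("no precursor quantities for this protein")
  sum(sort(q, decreasing = TRUE)[seq_len(min(3L, length(q)))])
}
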