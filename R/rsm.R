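# Representative spectral matrices (RSMs).
#
# An RSM bundles, for one precursor at one candidate RT location, 170 ion
# chromatograms over a 12-cycle window, in eight named row blocks:
#
#   library@r (20)     top-20 library fragments at the basic resolution r,
#                      sorted by the sum of Pearson correlations with the
#                      other library rows
#   library@0.2r (20)  same fragments, narrower extraction window
#   library@0.45r (20) same fragments, intermediate window
#   self (50)          all theoretical b/y fragments, sorted by correlation
#                      with the first library row
#   qt3 (10)           unfragmented precursor + M+1..M+4 isotopes in MS2
#   ms1 (10)           precursor at the three resolutions, M+1..M+4 and M-1
#                      isotopologues in MS1
#   iso (20)           (M+1)/q isotope of each library fragment
#   light (20)         (M-1)/q light isotopologue of each library fragment
#
# The qt3 and ms1 blocks enumerate 5 and 8 chromatograms respectively and
# are zero-padded to 10 rows each so that the full matrix totals 170 rows
# and part exclusion reproduces the 150/130/120/110/60/40/20 ablation
# series.

PART_ORDER <- c("library_r", "library_02r", "library_045r", "self", "qt3",
                "ms1", "iso", "light")
EXCLUDABLE_PARTS <- c("light", "iso", "qt3", "ms1", "self", "library_045r",
                      "library_02r")

#' RSM assembly parameters
#'
#' @param basic_resolution Basic extraction half-width r; the two extra
#'   library resolutions are 0.2*r and 0.45*r (narrower windows at the same
#'   centers).
#' @param resolution_unit "ppm" or "Da".
#' @param n_cycles RT width of the matrix in acquisition cycles.
#' @param excluded_parts Parts to omit (for ablation); any of
#'   \code{EXCLUDABLE_PARTS}.
#' @param n_library,n_self Per-resolution library rows and self rows.
#' @return An \code{rsm_params} list.
#' @export
rsm_params <- function(basic_resolution = 30, resolution_unit = c("ppm", "Da"),
                       n_cycles = 12L, excluded_parts = character(),
                       n_library = 20L, n_self = 50L) {
  resolution_unit <- match.arg(resolution_unit)
  stopifnot(n_cycles >= 3L, basic_resolution > 0)
  bad <- setdiff(excluded_parts, EXCLUDABLE_PARTS)
  if (length(bad)) stop("cannot exclude part(s): ", paste(bad, collapse = ", "))
  sizes <- c(library_r = n_library, library_02r = n_library,
             library_045r = n_library, self = n_self, qt3 = 10L, ms1 = 10L,
             iso = n_library, light = n_library)
  structure(list(basic_resolution = basic_resolution,
                 resolution_unit = resolution_unit,
                 n_cycles = as.integer(n_cycles),
                 excluded_parts = excluded_parts, sizes = sizes),
            class = "rsm_params")
}

rsm_layout <- function(params) {
  keep <- setdiff(PART_ORDER, params$excluded_parts)
  params$sizes[keep]
}

#' Pearson correlation between two chromatograms
#'
#' Standard Pearson correlation with the convention that any zero-variance
#' vector (e.g. an all-zero zero-filled row) has correlation 0 with
#' everything, so padded rows sort last deterministically.
#'
#' @param x,y Equal-length numeric vectors.
#' @export
xic_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("chromatogram lengths differ")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0 || !is.finite(sx) || !is.finite(sy)) return(0)
  stats::cor(x, y)
}

# Row-wise correlation matrix with the zero-variance-is-zero convention.
row_cor_matrix <- function(m) {
  xc <- m - rowMeans(m)
  s <- sqrt(rowSums(xc^2))
  ok <- s > 0
  C <- matrix(0, nrow(m), nrow(m))
  if (sum(ok) >= 1L) {
    Cok <- tcrossprod(xc[ok, , drop = FALSE] / s[ok])
    C[ok, ok] <- Cok
  }
  C
}

# Correlation of each row of m with vector v (zero-variance convention).
rows_cor_vector <- function(m, v) {
  vc <- v - mean(v)
  sv <- sqrt(sum(vc^2))
  if (sv == 0) return(numeric(nrow(m)))
  xc <- m - rowMeans(m)
  s <- sqrt(rowSums(xc^2))
  out <- as.vector(xc %*% vc)
  ifelse(s > 0, out / (s * sv), 0)
}

# All extraction targets for one precursor, computed once per entry; the
# full-gradient XIC matrices let RSMs at many candidate centers be sliced
# out cheaply.
#' Precompute full-gradient chromatograms for one precursor
#'
#' Extracts every chromatogram an RSM needs (library fragments at three
#' resolutions, theoretical self fragments, precursor/isotope traces in MS1
#' and MS2, fragment isotope and light-isotopologue traces) over the whole
#' gradient. \code{\link{assemble_rsm}} slices windows out of this bundle.
#'
#' @param run A \code{dia_run}.
#' @param entry A library entry.
#' @param params \code{\link{rsm_params}}.
#' @return An opaque bundle object used by \code{assemble_rsm}.
#' @export
precursor_xic_bundle <- function(run, entry, params = rsm_params()) {
  if (nrow(entry$fragments) == 0L) {
    stop("entry '", entry$modified_sequence, "' has no library fragments")
  }
  nL <- params$sizes[["library_r"]]
  w <- find_isolation_window(run, entry$precursor_mz)
  r <- params$basic_resolution
  hw <- function(mz, res) tolerance_half_width(mz, res, params$resolution_unit)

  # top library fragments by library intensity (stable order)
  fr <- entry$fragments
  sel <- order(-fr$library_intensity)[seq_len(min(nL, nrow(fr)))]
  lib_mz <- rep(NA_real_, nL)
  lib_q <- rep(NA_real_, nL)
  lib_int <- rep(0, nL)
  lib_mz[seq_along(sel)] <- fr$mz[sel]
  lib_q[seq_along(sel)] <- fr$charge[sel]
  lib_int[seq_along(sel)] <- fr$library_intensity[sel]

  theo <- theoretical_fragment_mzs(entry$modified_sequence,
                                   entry$precursor_charge)
  pmz <- entry$precursor_mz
  z <- entry$precursor_charge
  qt3_mz <- pmz + (0:4) * ISOTOPE_DELTA / z

  # one extraction pass over the MS2 spectra for all targets
  iso_mz <- lib_mz + ISOTOPE_DELTA / lib_q
  light_mz <- lib_mz - ISOTOPE_DELTA / lib_q
  ms2_mz <- c(lib_mz, lib_mz, lib_mz, iso_mz, light_mz, theo$mz, qt3_mz)
  ms2_hw <- c(hw(lib_mz, r), hw(lib_mz, 0.2 * r), hw(lib_mz, 0.45 * r),
              hw(iso_mz, r), hw(light_mz, r), hw(theo$mz, r), hw(qt3_mz, r))
  M2 <- xic_matrix(run$ms2[[w]], ms2_mz, ms2_hw)
  ends <- cumsum(c(nL, nL, nL, nL, nL, nrow(theo), 5L))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  take <- function(k) M2[starts[k]:ends[k], , drop = FALSE]

  ms1_mz <- c(pmz, pmz, pmz, pmz + (1:4) * ISOTOPE_DELTA / z,
              pmz - ISOTOPE_DELTA / z)
  ms1_hw <- c(hw(pmz, r), hw(pmz, 0.2 * r), hw(pmz, 0.45 * r),
              hw(ms1_mz[4:8], r))
  ms1 <- xic_matrix(run$ms1, ms1_mz, ms1_hw)

  structure(list(lib_r = take(1L), lib_02r = take(2L), lib_045r = take(3L),
                 iso = take(4L), light = take(5L), self = take(6L),
                 qt3 = take(7L), ms1 = ms1,
                 lib_intensity = lib_int, n_total = length(run$rt),
                 rt = run$rt, entry = entry, params = params),
            class = "dia_xic_bundle")
}

# Window column indices for a center cycle; 0 marks zero-padding outside
# the run (the apex stays at a fixed column).
window_columns <- function(center, n_cycles, n_total) {
  cols <- (center - floor(n_cycles / 2) + 1L):(center + ceiling(n_cycles / 2))
  ifelse(cols >= 1L & cols <= n_total, cols, 0L)
}

slice_window <- function(m, cols) {
  out <- matrix(0, nrow(m), length(cols))
  ok <- cols > 0L
  out[, ok] <- m[, cols[ok], drop = FALSE]
  out
}

# Matrix-assembly core shared by assemble_rsm and the batched scanners:
# returns the row-block matrix and the library row order.
rsm_matrix_at <- function(bundle, center_cycle, params) {
  cols <- window_columns(center_cycle, params$n_cycles, bundle$n_total)
  nL <- params$sizes[["library_r"]]
  nS <- params$sizes[["self"]]

  lib_r <- slice_window(bundle$lib_r, cols)
  C <- row_cor_matrix(lib_r)
  key <- rowSums(C) - diag(C)  # exclude self-pairing
  ord <- order(-key)           # stable: ties keep original index order
  lib_r <- lib_r[ord, , drop = FALSE]

  layout <- rsm_layout(params)
  mat <- matrix(0, sum(layout), length(cols))
  ends <- cumsum(layout)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  names(starts) <- names(layout)
  put <- function(part, m) {
    if (!part %in% names(layout)) return(invisible())
    i0 <- starts[[part]]
    mat[i0:(i0 + nrow(m) - 1L), ] <<- m
    invisible()
  }
  put("library_r", lib_r)
  put("library_02r", slice_window(bundle$lib_02r, cols)[ord, , drop = FALSE])
  put("library_045r", slice_window(bundle$lib_045r, cols)[ord, , drop = FALSE])

  if ("self" %in% names(layout)) {
    self <- slice_window(bundle$self, cols)
    if (nrow(self) > nS) {
      keep <- order(-rowSums(self))[seq_len(nS)]  # intensity-based filtering
      self <- self[sort(keep), , drop = FALSE]
    } else if (nrow(self) < nS) {
      self <- rbind(self, matrix(0, nS - nrow(self), length(cols)))
    }
    # zero-filled rows participate in the sort (correlation 0), so real
    # rows anti-correlated with the first library trace rank below them
    self_ord <- order(-rows_cor_vector(self, lib_r[1L, ]))
    put("self", self[self_ord, , drop = FALSE])
  }
  put("qt3", slice_window(bundle$qt3, cols))
  put("ms1", slice_window(bundle$ms1, cols))
  put("iso", slice_window(bundle$iso, cols)[ord, , drop = FALSE])
  put("light", slice_window(bundle$light, cols)[ord, , drop = FALSE])
  list(matrix = mat, layout = layout, library_order = ord)
}

#' Assemble an RSM at a candidate RT location
#'
#' @param x A \code{dia_run} (with \code{entry} given) or a bundle from
#'   \code{\link{precursor_xic_bundle}}.
#' @param entry Library entry (ignored when \code{x} is a bundle).
#' @param center_cycle Cycle index at which the window is centered; windows
#'   clipped at the run edges are zero-padded, not shifted.
#' @param params \code{\link{rsm_params}}.
#' @return A \code{dia_rsm}: the row-block matrix plus layout metadata.
#' @export
assemble_rsm <- function(x, entry = NULL, center_cycle, params = rsm_params()) {
  bundle <- if (inherits(x, "dia_xic_bundle")) x
            else precursor_xic_bundle(x, entry, params)
  params <- bundle$params
  core <- rsm_matrix_at(bundle, center_cycle, params)
  rt <- window_rt(bundle$rt, center_cycle, params$n_cycles)
  structure(list(matrix = core$matrix, layout = core$layout,
                 center_cycle = center_cycle,
                 rt = rt, library_order = core$library_order,
                 precursor = list(modified_sequence = bundle$entry$modified_sequence,
                                  precursor_charge = bundle$entry$precursor_charge,
                                  precursor_mz = bundle$entry$precursor_mz,
                                  protein_id = bundle$entry$protein_id,
                                  is_decoy = bundle$entry$is_decoy),
                 params = params),
            class = "dia_rsm")
}

# RT (seconds) per window column; columns padded beyond the run edges get
# linearly extrapolated times so areas stay well-defined.
window_rt <- function(rt, center, n_cycles) {
  idx <- (center - floor(n_cycles / 2) + 1L):(center + ceiling(n_cycles / 2))
  n <- length(rt)
  dt <- if (n > 1L) stats::median(diff(rt)) else 1
  ifelse(idx < 1L, rt[1L] + (idx - 1L) * dt,
         ifelse(idx > n, rt[n] + (idx - n) * dt, rt[pmin(pmax(idx, 1L), n)]))
}

#' @export
print.dia_rsm <- function(x, ...) {
  cat("<dia_rsm> ", nrow(x$matrix), " x ", ncol(x$matrix), " (",
      paste(names(x$layout), x$layout, sep = ":", collapse = " "),
      ") center cycle ", x$center_cycle, "\n", sep = "")
  invisible(x)
}

#' Block boundaries of an RSM
#' @param rsm A \code{dia_rsm}.
#' @return Named list of row index vectors, one per part.
#' @export
rsm_blocks <- function(rsm) {
  ends <- cumsum(rsm$layout)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  stats::setNames(Map(seq, starts, ends), names(rsm$layout))
}

#' Scale an RSM to [0, 1] by its global maximum
#'
#' All-zero matrices are returned unchanged; the operation is idempotent.
#'
#' @param rsm A \code{dia_rsm} or plain matrix.
#' @export
normalize_rsm <- function(rsm) {
  if (is.matrix(rsm)) {
    mx <- max(rsm)
    return(if (mx > 0) rsm / mx else rsm)
  }
  mx <- max(rsm$matrix)
  if (mx > 0) rsm$matrix <- rsm$matrix / mx
  rsm
}
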