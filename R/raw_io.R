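# DIA run I/O and extracted ion chromatograms.
#
# A run is held cycle-indexed: one MS1 spectrum plus one MS2 spectrum per
# isolation window per cycle. The cycle, not seconds, is the time axis for
# everything downstream; per-cycle RT in seconds is kept as metadata.

new_spectrum <- function(mz, intensity) {
  o <- order(mz)
  mz <- as.numeric(mz[o]); intensity <- as.numeric(intensity[o])
  list(mz = mz, intensity = intensity, cum = c(0, cumsum(intensity)))
}

EMPTY_SPECTRUM <- list(mz = numeric(), intensity = numeric(), cum = 0)

new_run <- function(rt, windows, ms1, ms2, source = "in-memory") {
  structure(list(rt = rt, windows = windows, ms1 = ms1, ms2 = ms2,
                 source = source), class = "dia_run")
}

#' @export
print.dia_run <- function(x, ...) {
  cat("<dia_run> ", length(x$rt), " cycles, ", nrow(x$windows),
      " isolation windows, RT ", round(min(x$rt), 1), "-",
      round(max(x$rt), 1), " s (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Number of cycles in a run
#' @param run A \code{dia_run}.
#' @export
n_cycles <- function(run) length(run$rt)

#' Load a centroided DIA run
#'
#' Reads an mzML or mzXML file (via mzR), groups spectra into acquisition
#' cycles at MS1 boundaries, and deduplicates the isolation window scheme
#' across cycles. Per-cycle retention time is taken from the MS1 scan.
#'
#' @param path Path to a centroided, cycle-structured DIA mzML/mzXML file.
#' @return A \code{dia_run}.
#' @export
load_run <- function(path) {
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- mzR::header(handle)
  if (!any(hdr$msLevel == 2L)) {
    stop("no MS2 spectra found: '", path, "' is not a DIA run")
  }
  if (any(hdr$centroided %in% FALSE)) {
    stop("profile-mode spectra detected in '", path,
         "'; centroid the data before loading")
  }
  ms1_idx <- which(hdr$msLevel == 1L)
  if (length(ms1_idx) == 0L) stop("no MS1 spectra found in '", path, "'")
  rt <- hdr$retentionTime[ms1_idx]
  if (any(diff(rt) <= 0)) stop("retention time is not strictly increasing")

  ms2 <- hdr$msLevel == 2L
  center <- ifelse(is.na(hdr$isolationWindowTargetMZ), hdr$precursorMZ,
                   hdr$isolationWindowTargetMZ)
  lo_off <- hdr$isolationWindowLowerOffset
  hi_off <- hdr$isolationWindowUpperOffset
  centers <- sort(unique(round(center[ms2], 6)))
  if (all(is.na(lo_off[ms2]))) {
    # infer fixed-width windows from the spacing of window centers
    half <- if (length(centers) > 1L) min(diff(centers)) / 2 else 12.5
    lo_off[ms2] <- half; hi_off[ms2] <- half
  }
  win_lo <- vapply(centers, function(cc) {
    i <- which(ms2 & round(center, 6) == cc)[1L]; center[i] - lo_off[i]
  }, numeric(1))
  win_hi <- vapply(centers, function(cc) {
    i <- which(ms2 & round(center, 6) == cc)[1L]; center[i] + hi_off[i]
  }, numeric(1))
  windows <- cbind(lo = win_lo, hi = win_hi, center = centers)

  cycle_of <- findInterval(seq_len(nrow(hdr)), ms1_idx)
  n_cyc <- length(ms1_idx)
  pk <- mzR::peaks(handle)
  if (!is.list(pk)) pk <- list(pk)
  ms1_spec <- lapply(ms1_idx, function(i)
    new_spectrum(pk[[i]][, 1], pk[[i]][, 2]))
  ms2_spec <- lapply(seq_along(centers), function(w)
    rep(list(EMPTY_SPECTRUM), n_cyc))
  for (i in which(ms2)) {
    cyc <- cycle_of[i]
    if (cyc < 1L) next
    w <- match(round(center[i], 6), centers)
    ms2_spec[[w]][[cyc]] <- new_spectrum(pk[[i]][, 1], pk[[i]][, 2])
  }
  new_run(rt, windows, ms1_spec, ms2_spec, source = path)
}

#' Write a run as centroided mzML or mzXML
#'
#' @param run A \code{dia_run}.
#' @param path Output path.
#' @param format "mzml" or "mzxml".
#' @export
write_run <- function(run, path, format = c("mzml", "mzxml")) {
  format <- match.arg(format)
  n_cyc <- length(run$rt)
  n_win <- nrow(run$windows)
  per_cycle <- 1L + n_win
  n_spec <- n_cyc * per_cycle
  pk <- vector("list", n_spec)
  msLevel <- integer(n_spec); rts <- numeric(n_spec)
  precMZ <- rep(NA_real_, n_spec); lo_off <- rep(NA_real_, n_spec)
  hi_off <- rep(NA_real_, n_spec); precScan <- rep(NA_integer_, n_spec)
  k <- 0L
  for (cyc in seq_len(n_cyc)) {
    k <- k + 1L
    pk[[k]] <- cbind(mz = run$ms1[[cyc]]$mz,
                     intensity = run$ms1[[cyc]]$intensity)
    msLevel[k] <- 1L; rts[k] <- run$rt[cyc]
    ms1_scan <- k
    for (w in seq_len(n_win)) {
      k <- k + 1L
      sp <- run$ms2[[w]][[cyc]]
      pk[[k]] <- cbind(mz = sp$mz, intensity = sp$intensity)
      msLevel[k] <- 2L
      rts[k] <- run$rt[cyc] + w * 1e-3  # distinct, ordered scan times
      precMZ[k] <- run$windows[w, "center"]
      lo_off[k] <- run$windows[w, "center"] - run$windows[w, "lo"]
      hi_off[k] <- run$windows[w, "hi"] - run$windows[w, "center"]
      precScan[k] <- ms1_scan
    }
  }
  # mzR refuses empty peak arrays; emit a negligible sentinel peak instead
  empty <- vapply(pk, nrow, integer(1)) == 0L
  pk[empty] <- list(cbind(mz = 100.0, intensity = 0.0))
  hdr <- data.frame(
    seqNum = seq_len(n_spec), acquisitionNum = seq_len(n_spec),
    msLevel = msLevel, polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = rts,
    basePeakMZ = vapply(pk, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pk, function(p)
      if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(msLevel == 2L, 27, 0), ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) if (nrow(p)) min(p[, 1]) else 0, numeric(1)),
    highMZ = vapply(pk, function(p) if (nrow(p)) max(p[, 1]) else 0, numeric(1)),
    precursorScanNum = ifelse(is.na(precScan), 0L, precScan),
    precursorMZ = ifelse(is.na(precMZ), 0, precMZ),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n_spec)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = precMZ, isolationWindowLowerOffset = lo_off,
    isolationWindowUpperOffset = hi_off,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pk, path, header = hdr, outformat = format)
  invisible(path)
}

#' Find the isolation window containing an m/z
#'
#' When overlapping windows both contain the m/z, the window whose center
#' is nearest is chosen.
#'
#' @param run A \code{dia_run}.
#' @param mz Precursor m/z.
#' @return Window index.
#' @export
find_isolation_window <- function(run, mz) {
  hits <- which(run$windows[, "lo"] <= mz & mz <= run$windows[, "hi"])
  if (length(hits) == 0L) {
    stop("precursor m/z ", round(mz, 4), " falls outside every isolation window")
  }
  hits[which.min(abs(run$windows[hits, "center"] - mz))]
}

# Vectorised range-sum over one spectrum: total intensity of all centroid
# peaks inside [lo_i, hi_i] for each target i.
spectrum_range_sums <- function(sp, lo, hi) {
  if (length(sp$mz) == 0L) return(numeric(length(lo)))
  i1 <- findInterval(lo - 1e-9, sp$mz)
  i2 <- findInterval(hi, sp$mz)
  sp$cum[i2 + 1L] - sp$cum[i1 + 1L]
}

# Full-gradient XIC matrix: one row per target m/z, one column per cycle.
xic_matrix <- function(spectra, mzs, half_widths, cycles = NULL) {
  if (is.null(cycles)) cycles <- seq_along(spectra)
  out <- matrix(0, nrow = length(mzs), ncol = length(cycles))
  keep <- !is.na(mzs)
  if (!any(keep)) return(out)
  lo <- mzs[keep] - half_widths[keep]
  hi <- mzs[keep] + half_widths[keep]
  for (j in seq_along(cycles)) {
    out[keep, j] <- spectrum_range_sums(spectra[[cycles[j]]], lo, hi)
  }
  out
}

tolerance_half_width <- function(mz, tolerance, unit) {
  if (unit == "ppm") mz * tolerance * 1e-6 else rep(tolerance, length(mz))
}

#' Extract an ion chromatogram
#'
#' Per cycle, sums the intensities of all centroid peaks within the
#' tolerance window around \code{target_mz}; cycles with no matching peak
#' contribute zero.
#'
#' @param run A \code{dia_run}.
#' @param target_mz Target m/z (Th).
#' @param tolerance Half-width of the extraction window.
#' @param unit "ppm" (window is \code{target_mz * (1 +/- tol*1e-6)}) or "Da".
#' @param level "ms2" or "ms1".
#' @param window_mz For MS2: the precursor m/z selecting the isolation
#'   window (defaults to \code{target_mz}).
#' @param cycles Cycle indices to extract (default: all).
#' @return Numeric vector of intensities, one per requested cycle.
#' @export
extract_xic <- function(run, target_mz, tolerance, unit = c("ppm", "Da"),
                        level = c("ms2", "ms1"), window_mz = NULL,
                        cycles = NULL) {
  unit <- match.arg(unit); level <- match.arg(level)
  spectra <- if (level == "ms1") {
    run$ms1
  } else {
    w <- find_isolation_window(run, if (is.null(window_mz)) target_mz else window_mz)
    run$ms2[[w]]
  }
  hw <- tolerance_half_width(target_mz, tolerance, unit)
  drop(xic_matrix(spectra, target_mz, hw, cycles))
}
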