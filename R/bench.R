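# Benchmarking utilities: the two-species proxy FDR and the
# deamidation / pseudo mass-shift confidence test.

#' Build a two-species benchmark library
#'
#' Foreign precursors whose sequences occur in the sample library are
#' discarded; a seeded random subset of exactly |sample library| foreign
#' precursors is spiked in; every precursor of both species is truncated
#' to its six highest-intensity fragments. The species of each entry is
#' recorded in its \code{species} field.
#'
#' @param sample_lib,foreign_lib \code{dia_speclib} objects (targets only).
#' @param seed Integer seed for the foreign subset draw.
#' @export
build_two_species_library <- function(sample_lib, foreign_lib, seed = 1L) {
  sample_seqs <- vapply(sample_lib$entries, `[[`, character(1),
                        "modified_sequence")
  foreign <- Filter(function(e) !(e$modified_sequence %in% sample_seqs),
                    foreign_lib$entries)
  n_needed <- length(sample_lib$entries)
  if (length(foreign) < n_needed) {
    stop("insufficient foreign precursors after overlap filtering: ",
         length(foreign), " available, ", n_needed, " needed")
  }
  pick <- with_local_seed(seed, sample(length(foreign), n_needed))
  top6 <- function(e, species) {
    keep <- order(-e$fragments$library_intensity)[
      seq_len(min(6L, nrow(e$fragments)))]
    e$fragments <- e$fragments[sort(keep), , drop = FALSE]
    e$species <- species
    e
  }
  entries <- c(lapply(sample_lib$entries, top6, species = "sample"),
               lapply(foreign[pick], top6, species = "foreign"))
  new_speclib(entries)
}

#' Species labels of a library's entries
#' @param lib A library from \code{\link{build_two_species_library}}.
#' @export
library_species <- function(lib) {
  vapply(lib$entries, function(e)
    if (is.null(e$species)) NA_character_ else e$species, character(1))
}

#' Two-species proxy FDR curve
#'
#' For each foreign precursor's score taken as a cutoff, the proxy FDR is
#' the number of foreign precursors scoring at or above the cutoff divided
#' by the number of all precursors scoring at or above it, paired with the
#' count of true-species precursors above the cutoff.
#'
#' @param results A scored target table (no decoys) with
#'   \code{discriminant_score}.
#' @param species Character vector ("sample"/"foreign") aligned with
#'   \code{results} rows.
#' @return data.frame with \code{cutoff}, \code{proxy_fdr},
#'   \code{n_true_species}, sorted by decreasing cutoff.
#' @export
proxy_fdr_curve <- function(results, species) {
  stopifnot(nrow(results) == length(species))
  if (!any(species == "foreign")) stop("no foreign-species results")
  s <- results$discriminant_score
  cutoffs <- sort(unique(s[species == "foreign"]), decreasing = TRUE)
  out <- do.call(rbind, lapply(cutoffs, function(cc) {
    above <- s >= cc
    data.frame(cutoff = cc,
               proxy_fdr = sum(above & species == "foreign") / sum(above),
               n_true_species = sum(above & species == "sample"))
  }))
  rownames(out) <- NULL
  out
}

#' Proxy FDR at a given score cutoff
#' @inheritParams proxy_fdr_curve
#' @param cutoff Score cutoff.
#' @export
proxy_fdr_at <- function(results, species, cutoff) {
  above <- results$discriminant_score >= cutoff
  if (!any(above)) return(0)
  sum(above & species == "foreign") / sum(above)
}

#' Deamidation mass-shift confidence test
#'
#' Analyzes the same run twice with identical settings and seeds: once
#' with the given library (true deamidation shift) and once with its
#' pseudo mass-shift version (every deamidation-bearing ion moved by
#' \code{(1.0227 - 0.9840)/C}). A trustworthy engine identifies many more
#' deamidated precursors with the true shift.
#'
#' @param run A \code{dia_run}.
#' @param deamid_lib Target library containing deamidated precursors.
#' @param model Trained \code{dia_rep_model}.
#' @param fdr q-value threshold for counting identifications.
#' @param seed Integer seed shared by both analyses.
#' @param ... Passed to \code{\link{dia_pipeline}}.
#' @return List with \code{n_true_shift} and \code{n_pseudo_shift}
#'   (deamidated precursors passing \code{fdr}), \code{dds_true} and
#'   \code{dds_pseudo} (best-candidate dds of every deamidated precursor
#'   in each analysis; the dds scale is shared because both analyses use
#'   the same representation model, so it quantifies how much elution
#'   evidence the mass shift removes), and the two result objects.
#' @export
deamidation_confidence_test <- function(run, deamid_lib, model, fdr = 0.01,
                                        seed = 1L, ...) {
  is_deam <- vapply(deamid_lib$entries, function(e)
    grepl("(UniMod:7)", e$modified_sequence, fixed = TRUE), logical(1))
  if (!any(is_deam)) stop("library contains no deamidated precursors")
  pseudo_lib <- build_pseudo_mod_library(deamid_lib)
  deam_rows <- function(res) {
    r <- res$results
    r[!r$is_decoy & grepl("(UniMod:7)", r$modified_sequence, fixed = TRUE), ,
      drop = FALSE]
  }
  res_true <- dia_pipeline(run, deamid_lib, model, seed = seed, ...)
  res_pseudo <- dia_pipeline(run, pseudo_lib, model, seed = seed, ...)
  dt <- deam_rows(res_true)
  dp <- deam_rows(res_pseudo)
  list(n_true_shift = sum(dt$q_value <= fdr),
       n_pseudo_shift = sum(dp$q_value <= fdr),
       dds_true = dt$dds, dds_pseudo = dp$dds,
       true = res_true, pseudo = res_pseudo)
}
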