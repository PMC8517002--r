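# Spectral library handling: transition-list parsing/writing, theoretical
# fragment m/z computation, and pseudo mass-shift libraries for the
# deamidation confidence benchmark.

PROTON_MASS <- 1.007276
H2O_MASS <- 18.010565
ISOTOPE_DELTA <- 1.0033548  # 13C - 12C
DEAMIDATION_SHIFT <- 0.9840  # printed monoisotopic delta for N/Q deamidation
PSEUDO_DEAMIDATION_SHIFT <- 1.0227

# Monoisotopic residue masses
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# Built-in modification table (UniMod accessions); monoisotopic deltas.
UNIMOD_MASS <- c(
  "1" = 42.010565,   # acetyl
  "4" = 57.021464,   # carbamidomethyl
  "7" = 0.984016,    # deamidation (NH -> O)
  "35" = 15.994915)  # oxidation

#' Tokenize a modified peptide sequence
#'
#' Splits a sequence with UniMod-style bracketed tags (e.g.
#' \code{"PEPTC(UniMod:4)IDE"}) into one token per residue, carrying the
#' modification mass with the residue it annotates.
#'
#' @param sequence Modified sequence string.
#' @return A data.frame with columns \code{residue}, \code{mod} (UniMod
#'   accession or \code{NA}), \code{mass} (residue + modification mass) and
#'   \code{n_deamidation} (1 where the residue carries UniMod:7).
#' @export
parse_modified_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  toks <- regmatches(sequence,
    gregexpr("[A-Za-z](\\(UniMod:[0-9]+\\))?|.", sequence))[[1]]
  residue <- substr(toks, 1L, 1L)
  bad <- !(residue %in% names(RESIDUE_MASS)) | nchar(gsub(
    "^[A-Z](\\(UniMod:[0-9]+\\))?$", "", toks)) > 0
  if (any(bad)) {
    stop("unknown residue or modification token: '", toks[which(bad)[1L]],
         "' in sequence '", sequence, "'")
  }
  mod <- rep(NA_character_, length(toks))
  has_mod <- nchar(toks) > 1L
  mod[has_mod] <- sub("^[A-Z]\\(UniMod:([0-9]+)\\)$", "\\1", toks[has_mod])
  unknown <- has_mod & !(mod %in% names(UNIMOD_MASS))
  if (any(unknown)) {
    stop("unknown modification tag: '", toks[which(unknown)[1L]], "'")
  }
  mass <- unname(RESIDUE_MASS[residue])
  mass[has_mod] <- mass[has_mod] + unname(UNIMOD_MASS[mod[has_mod]])
  data.frame(residue = residue, mod = mod, mass = mass,
             n_deamidation = as.integer(has_mod & mod == "7"),
             stringsAsFactors = FALSE)
}

#' Neutral monoisotopic mass of a (modified) peptide
#' @param sequence Modified sequence string.
#' @return Neutral mass in Da.
#' @export
peptide_neutral_mass <- function(sequence) {
  sum(parse_modified_sequence(sequence)$mass) + H2O_MASS
}

#' Precursor m/z of a peptide at a given charge
#' @param sequence Modified sequence string.
#' @param charge Positive integer charge.
#' @export
precursor_mz <- function(sequence, charge) {
  stopifnot(charge >= 1)
  (peptide_neutral_mass(sequence) + charge * PROTON_MASS) / charge
}

#' Enumerate theoretical b/y fragment ions
#'
#' All b- and y-series ions over every cleavage position. Fragment charges
#' follow the precursor charge: \{1\} for precursors of charge <= 2, \{1, 2\}
#' for higher charges.
#'
#' @param sequence Modified sequence string.
#' @param precursor_charge Precursor charge state.
#' @return data.frame with columns \code{annotation} (e.g. "b3"),
#'   \code{series}, \code{index}, \code{charge}, \code{mz} and
#'   \code{n_deamidation} (deamidated residues inside the fragment), ordered
#'   by (series, index, charge).
#' @export
theoretical_fragment_mzs <- function(sequence, precursor_charge) {
  stopifnot(precursor_charge >= 1)
  tk <- parse_modified_sequence(sequence)
  L <- nrow(tk)
  if (L < 2L) stop("peptide must have at least two residues")
  charges <- if (precursor_charge <= 2) 1L else c(1L, 2L)
  b_neutral <- cumsum(tk$mass)[-L]
  y_neutral <- cumsum(rev(tk$mass))[-L] + H2O_MASS  # y_i = last i residues
  b_deam <- cumsum(tk$n_deamidation)[-L]
  y_deam <- cumsum(rev(tk$n_deamidation))[-L]
  out <- do.call(rbind, lapply(charges, function(q) {
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = rep(seq_len(L - 1L), 2L),
      charge = q,
      mz = (c(b_neutral, y_neutral) + q * PROTON_MASS) / q,
      n_deamidation = c(b_deam, y_deam),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  out$annotation <- paste0(out$series, out$index)
  rownames(out) <- NULL
  out[, c("annotation", "series", "index", "charge", "mz", "n_deamidation")]
}

#' Apply the pseudo mass-shift used in the deamidation confidence test
#'
#' Replaces the true deamidation shift on an ion by a nearby pseudo shift:
#' the returned m/z is \code{mz + n_mods * (pseudo_shift - true_shift) /
#' ion_charge}.
#'
#' @param mz Ion m/z.
#' @param n_mods Number of deamidations carried by the ion.
#' @param ion_charge Ion charge.
#' @param true_shift,pseudo_shift Mass shifts in Da.
#' @export
apply_pseudo_modification_shift <- function(mz, n_mods, ion_charge,
                                            true_shift = DEAMIDATION_SHIFT,
                                            pseudo_shift = PSEUDO_DEAMIDATION_SHIFT) {
  if (any(n_mods < 0)) stop("n_mods must be >= 0")
  if (any(ion_charge < 1)) stop("ion_charge must be >= 1")
  mz + n_mods * (pseudo_shift - true_shift) / ion_charge
}

# Default OpenSWATH-style transition-list column names.
default_library_dialect <- function() {
  list(precursor_mz = "PrecursorMz", product_mz = "ProductMz",
       library_intensity = "LibraryIntensity",
       normalized_rt = "NormalizedRetentionTime",
       peptide_sequence = "PeptideSequence",
       modified_sequence = "FullUniModPeptideName",
       precursor_charge = "PrecursorCharge", product_charge = "ProductCharge",
       fragment_type = "FragmentType", fragment_series = "FragmentSeriesNumber",
       protein = "ProteinName", decoy = "decoy")
}

#' Parse a transition-list spectral library
#'
#' Reads a tab-separated transition list (one row per fragment ion) and
#' groups rows into one entry per (modified sequence, precursor charge,
#' decoy flag). All fragment rows are kept verbatim; any top-N fragment
#' selection happens later, at matrix assembly.
#'
#' @param path Path to a TSV file.
#' @param dialect Named list mapping canonical roles to file column names;
#'   see \code{default_library_dialect()}. The \code{decoy} column is
#'   optional (absent means all targets).
#' @return A \code{dia_speclib} object: a list of entries, each with
#'   \code{modified_sequence}, \code{precursor_mz}, \code{precursor_charge},
#'   \code{normalized_rt}, \code{protein_id}, \code{is_decoy} and a
#'   \code{fragments} data.frame.
#' @export
parse_library <- function(path, dialect = default_library_dialect()) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty spectral library: ", path)
  required <- c("precursor_mz", "product_mz", "library_intensity",
                "normalized_rt", "modified_sequence", "precursor_charge",
                "product_charge", "fragment_type", "fragment_series",
                "protein")
  for (role in required) {
    col <- dialect[[role]]
    if (is.null(col) || !(col %in% names(df))) {
      stop("library is missing required column '",
           if (is.null(col)) role else col, "' (role: ", role, ")")
    }
  }
  gv <- function(role) df[[dialect[[role]]]]
  is_decoy <- if (!is.null(dialect$decoy) && dialect$decoy %in% names(df)) {
    as.logical(as.integer(gv("decoy")))
  } else rep(FALSE, nrow(df))
  key <- paste(gv("modified_sequence"), gv("precursor_charge"),
               as.integer(is_decoy), sep = "|")
  idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
  entries <- lapply(idx, function(i) {
    list(modified_sequence = gv("modified_sequence")[i[1L]],
         peptide_sequence = if (!is.null(dialect$peptide_sequence) &&
                                dialect$peptide_sequence %in% names(df))
           df[[dialect$peptide_sequence]][i[1L]]
         else gsub("\\(UniMod:[0-9]+\\)", "", gv("modified_sequence")[i[1L]]),
         precursor_mz = as.numeric(gv("precursor_mz")[i[1L]]),
         precursor_charge = as.integer(gv("precursor_charge")[i[1L]]),
         normalized_rt = as.numeric(gv("normalized_rt")[i[1L]]),
         protein_id = as.character(gv("protein")[i[1L]]),
         is_decoy = is_decoy[i[1L]],
         fragments = data.frame(
           annotation = paste0(gv("fragment_type")[i], gv("fragment_series")[i]),
           series = as.character(gv("fragment_type")[i]),
           index = as.integer(gv("fragment_series")[i]),
           charge = as.integer(gv("product_charge")[i]),
           mz = as.numeric(gv("product_mz")[i]),
           library_intensity = as.numeric(gv("library_intensity")[i]),
           stringsAsFactors = FALSE))
  })
  names(entries) <- NULL
  new_speclib(entries)
}

new_speclib <- function(entries) {
  structure(list(entries = entries), class = "dia_speclib")
}

#' @export
length.dia_speclib <- function(x) length(x$entries)

#' @export
`[.dia_speclib` <- function(x, i) new_speclib(x$entries[i])

#' @export
print.dia_speclib <- function(x, ...) {
  n_dec <- sum(vapply(x$entries, `[[`, logical(1), "is_decoy"))
  cat("<dia_speclib> ", length(x$entries), " precursors (",
      length(x$entries) - n_dec, " targets, ", n_dec, " decoys)\n", sep = "")
  invisible(x)
}

#' Combine spectral libraries
#' @param ... \code{dia_speclib} objects.
#' @export
concat_libraries <- function(...) {
  new_speclib(do.call(c, lapply(list(...), `[[`, "entries")))
}

entry_key <- function(e) {
  paste(e$modified_sequence, e$precursor_charge, as.integer(e$is_decoy),
        sep = "|")
}

#' Write a spectral library as a transition-list TSV
#'
#' Inverse of \code{\link{parse_library}}: numeric fields are printed with
#' shortest round-trip formatting so a parse/write cycle reproduces a
#' well-formed fixture file's values exactly.
#'
#' @param lib A \code{dia_speclib}.
#' @param path Output path.
#' @param dialect Column-name mapping, as in \code{parse_library}.
#' @export
write_library <- function(lib, path, dialect = default_library_dialect()) {
  rows <- lapply(lib$entries, function(e) {
    nf <- nrow(e$fragments)
    data.frame(
      PrecursorMz = rep(e$precursor_mz, nf),
      ProductMz = e$fragments$mz,
      LibraryIntensity = e$fragments$library_intensity,
      NormalizedRetentionTime = rep(e$normalized_rt, nf),
      PeptideSequence = rep(e$peptide_sequence, nf),
      FullUniModPeptideName = rep(e$modified_sequence, nf),
      PrecursorCharge = rep(e$precursor_charge, nf),
      ProductCharge = e$fragments$charge,
      FragmentType = e$fragments$series,
      FragmentSeriesNumber = e$fragments$index,
      ProteinName = rep(e$protein_id, nf),
      decoy = rep(as.integer(e$is_decoy), nf),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df) <- vapply(c("precursor_mz", "product_mz", "library_intensity",
                        "normalized_rt", "peptide_sequence",
                        "modified_sequence", "precursor_charge",
                        "product_charge", "fragment_type", "fragment_series",
                        "protein", "decoy"),
                      function(r) dialect[[r]], character(1))
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           vapply(x, function(v) as.character(v), character(1)))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pseudo mass-shift library for the deamidation confidence test
#'
#' Every deamidation-bearing ion (precursor and b/y fragments spanning a
#' deamidated residue) has its m/z moved from the true deamidation shift to
#' a nearby pseudo shift via
#' \code{\link{apply_pseudo_modification_shift}}. A confident scoring engine
#' should identify far fewer precursors with the pseudo-shift library.
#'
#' @param lib A \code{dia_speclib} containing deamidated entries.
#' @inheritParams apply_pseudo_modification_shift
#' @return The shifted library.
#' @export
build_pseudo_mod_library <- function(lib, true_shift = DEAMIDATION_SHIFT,
                                     pseudo_shift = PSEUDO_DEAMIDATION_SHIFT) {
  entries <- lapply(lib$entries, function(e) {
    tk <- parse_modified_sequence(e$modified_sequence)
    n_total <- sum(tk$n_deamidation)
    if (n_total == 0L) return(e)
    e$precursor_mz <- apply_pseudo_modification_shift(
      e$precursor_mz, n_total, e$precursor_charge, true_shift, pseudo_shift)
    L <- nrow(tk)
    cum_b <- cumsum(tk$n_deamidation)
    cum_y <- rev(cumsum(rev(tk$n_deamidation)))
    n_frag <- ifelse(e$fragments$series == "b",
                     cum_b[pmin(e$fragments$index, L)],
                     cum_y[pmax(L - e$fragments$index + 1L, 1L)])
    e$fragments$mz <- apply_pseudo_modification_shift(
      e$fragments$mz, n_frag, e$fragments$charge, true_shift, pseudo_shift)
    e
  })
  new_speclib(entries)
}
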