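# Decoy library generation: per-target in-silico negatives for
# positive-unlabeled rescoring and target-decoy FDR estimation.

DECOY_METHODS <- c("shuffle", "reverse", "pseudo-reverse", "mutate", "shift")

# Fixed residue substitution table for the mutate method (an involution over
# the 20 residues, chosen so every residue maps to a different one).
MUTATE_SWAP <- c(
  G = "A", A = "G", S = "T", T = "S", P = "V", V = "P", C = "M", M = "C",
  L = "F", F = "L", I = "W", W = "I", N = "Q", Q = "N", D = "E", E = "D",
  K = "R", R = "K", H = "Y", Y = "H")

# Per-entry RNG stream derived from (seed, sequence) so decoy generation is
# independent of library order.
entry_stream_seed <- function(seed, sequence) {
  h <- 0
  for (v in utf8ToInt(sequence)) h <- (h * 31 + v) %% 2147480009
  as.integer((h + as.numeric(seed) * 7919) %% 2147480009)
}

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

decoy_sequence_tokens <- function(tokens, method, stream_seed) {
  L <- length(tokens)
  switch(method,
    "shuffle" = with_local_seed(stream_seed, {
      head <- tokens[-L]
      c(head[sample.int(L - 1L)], tokens[L])
    }),
    "reverse" = rev(tokens),
    "pseudo-reverse" = c(rev(tokens[-L]), tokens[L]),
    "mutate" = {
      pos <- unique(pmin(pmax(c(2L, ceiling(L / 2), L - 1L), 1L), L))
      out <- tokens
      for (p in pos) {
        res <- substr(out[p], 1L, 1L)
        if (res %in% names(MUTATE_SWAP)) {
          out[p] <- paste0(MUTATE_SWAP[[res]], substring(out[p], 2L))
        }
      }
      out
    },
    "shift" = tokens,
    stop("unknown decoy method: ", method))
}

sequence_tokens <- function(sequence) {
  tk <- parse_modified_sequence(sequence)
  ifelse(is.na(tk$mod), tk$residue,
         paste0(tk$residue, "(UniMod:", tk$mod, ")"))
}

#' Generate a decoy entry for one target precursor
#'
#' Transforms the target sequence by one of the five integrated methods
#' (\code{shuffle}, \code{reverse}, \code{pseudo-reverse}, \code{mutate},
#' \code{shift}) and recomputes fragment m/z values from the decoy sequence
#' for the annotated (series, index, charge) of each target fragment.
#' \code{shift} instead leaves the sequence untouched and moves every
#' fragment m/z by \code{shift_da / charge}. Modifications travel with
#' their residues; shuffling keeps the C-terminal (tryptic anchor) residue
#' fixed and is seeded per entry so results do not depend on library order.
#'
#' @param entry A target library entry.
#' @param method One of \code{DECOY_METHODS}.
#' @param seed Library-level integer seed.
#' @param forbidden Character vector of sequences the decoy must differ
#'   from (typically all target sequences); shuffles are re-drawn up to
#'   \code{retry} times.
#' @param shift_da Fragment m/z offset (Da per charge) for \code{shift}.
#' @param retry Maximum re-draws for the shuffle method.
#' @return A decoy entry, or \code{NULL} if no distinct sequence could be
#'   produced within the retry limit (a warning is raised).
#' @export
generate_decoy <- function(entry, method = "shuffle", seed = 1L,
                           forbidden = character(), shift_da = 10,
                           retry = 10L) {
  method <- match.arg(method, DECOY_METHODS)
  if (isTRUE(entry$is_decoy)) stop("entry is already a decoy")
  tokens <- sequence_tokens(entry$modified_sequence)
  out <- entry
  out$is_decoy <- TRUE
  out$protein_id <- paste0("DECOY_", entry$protein_id)
  if (method == "shift") {
    out$fragments$mz <- entry$fragments$mz + shift_da / entry$fragments$charge
    return(out)
  }
  stream <- entry_stream_seed(seed, entry$modified_sequence)
  dec <- NULL
  for (attempt in seq_len(max(1L, retry))) {
    cand <- decoy_sequence_tokens(tokens, method, stream + attempt - 1L)
    seq_cand <- paste(cand, collapse = "")
    if (!(seq_cand %in% forbidden) && seq_cand != entry$modified_sequence) {
      dec <- seq_cand
      break
    }
    if (method != "shuffle") break  # deterministic methods cannot re-draw
  }
  if (is.null(dec)) {
    warning("could not generate a distinct decoy for '",
            entry$modified_sequence, "' (", method, "); entry skipped")
    return(NULL)
  }
  out$modified_sequence <- dec
  out$peptide_sequence <- gsub("\\(UniMod:[0-9]+\\)", "", dec)
  out$precursor_mz <- precursor_mz(dec, entry$precursor_charge)
  theo <- theoretical_fragment_mzs(dec, 3L)  # charges 1 and 2 available
  key <- paste(theo$series, theo$index, theo$charge)
  fk <- paste(entry$fragments$series, entry$fragments$index,
              entry$fragments$charge)
  m <- match(fk, key)
  if (anyNA(m)) {
    warning("fragment annotation not derivable for decoy of '",
            entry$modified_sequence, "'; entry skipped")
    return(NULL)
  }
  out$fragments$mz <- theo$mz[m]
  out
}

#' Generate one decoy per target in a library
#'
#' @param lib A \code{dia_speclib} (decoy entries, if any, are ignored).
#' @param method Decoy generation method; the default mirrors common
#'   peptide-centric practice (\code{shuffle}).
#' @param seed Integer seed.
#' @param shift_da Offset for the \code{shift} method.
#' @return A \code{dia_speclib} holding the original targets followed by
#'   their decoys.
#' @export
generate_decoy_library <- function(lib, method = "shuffle", seed = 1L,
                                   shift_da = 10) {
  targets <- Filter(function(e) !e$is_decoy, lib$entries)
  forbidden <- vapply(targets, `[[`, character(1), "modified_sequence")
  decoys <- lapply(targets, generate_decoy, method = method, seed = seed,
                   forbidden = forbidden, shift_da = shift_da)
  decoys <- Filter(Negate(is.null), decoys)
  new_speclib(c(targets, decoys))
}
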