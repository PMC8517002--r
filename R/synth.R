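# Synthetic DIA experiments: a spectral library, a centroided
# cycle-structured run and the ground truth needed to validate every other
# module. Present precursors produce Gaussian elution peaks whose apexes
# follow a known library-RT -> run-RT linear map; fragment peak heights are
# proportional to library intensities times a per-precursor abundance; MS1
# traces carry an isotope envelope; MS2 spectra carry fragment peaks, their
# first isotopes, co-eluting interference peptides and a sparse noise
# floor. Centroid m/z values receive Gaussian ppm jitter.

AMINO_ACIDS <- names(RESIDUE_MASS)[names(RESIDUE_MASS) != "I"]  # avoid I/L ambiguity

#' Configuration for a synthetic DIA experiment
#'
#' @param n_precursors Number of library precursors.
#' @param fraction_present Fraction of library precursors actually present
#'   in the sample (the rest are planted absentees).
#' @param rt_slope,rt_intercept Library normalized RT -> run seconds map.
#' @param nrt_range Range of library normalized RTs.
#' @param peak_width_s Gaussian elution sigma (seconds); per-precursor
#'   jitter of +/-20 percent is applied.
#' @param cycle_time_s Acquisition cycle time (~3 s on most instruments).
#' @param n_cycles_total Number of acquisition cycles in the run.
#' @param window_range,n_windows Fixed-width isolation window scheme.
#' @param noise_peaks Mean number of noise peaks per spectrum (Poisson).
#' @param noise_floor Mean intensity of noise peaks (exponential); the
#'   default is ~1 percent of the median fragment apex height.
#' @param interference_rate Co-eluting unlisted peptides, as a fraction of
#'   \code{n_precursors}.
#' @param isotope_model MS1 isotope envelope heights for M..M+4.
#' @param ms2_isotope_ratio Height of a fragment's M+1 peak relative to its
#'   monoisotopic peak.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param mz_jitter_ppm Centroid m/z jitter (1 sd, ppm).
#' @param n_fragments Range of library fragments per precursor.
#' @param charges,charge_probs Precursor charge states and probabilities.
#' @param deamidation_fraction Fraction of peptides carrying one
#'   deamidated residue (for the mass-shift confidence benchmark).
#' @param condition_ratios Optional per-group fold changes (condition 2 vs
#'   condition 1) for two-condition quantification benchmarks; precursors
#'   are assigned to groups round-robin.
#' @param seed Integer seed; the same seed reproduces the experiment
#'   exactly.
#' @export
synth_config <- function(n_precursors = 200L, fraction_present = 0.7,
                         rt_slope = 3, rt_intercept = 30,
                         nrt_range = c(0, 100), peak_width_s = 4,
                         cycle_time_s = 3, n_cycles_total = 120L,
                         window_range = c(400, 1200), n_windows = 64L,
                         noise_peaks = 15, noise_floor = 1,
                         interference_rate = 0.1,
                         isotope_model = c(1, 0.55, 0.2, 0.06, 0.015),
                         ms2_isotope_ratio = 0.3,
                         abundance_meanlog = log(200), abundance_sdlog = 0.7,
                         mz_jitter_ppm = 2, n_fragments = c(6L, 15L),
                         charges = c(2L, 3L), charge_probs = c(0.7, 0.3),
                         deamidation_fraction = 0,
                         condition_ratios = NULL, seed = 1L) {
  stopifnot(fraction_present >= 0, fraction_present <= 1,
            interference_rate >= 0, peak_width_s > 0,
            deamidation_fraction >= 0, deamidation_fraction <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  cfg
}

synth_windows <- function(cfg) {
  edges <- seq(cfg$window_range[1L], cfg$window_range[2L],
               length.out = cfg$n_windows + 1L)
  cbind(lo = edges[-length(edges)], hi = edges[-1L],
        center = (edges[-length(edges)] + edges[-1L]) / 2)
}

# Random tryptic-like peptide with precursor m/z inside the window scheme.
random_peptide <- function(cfg, windows, deamidated = FALSE) {
  for (i in 1:200) {
    L <- sample(7:20, 1L)
    res <- c(sample(setdiff(AMINO_ACIDS, c("K", "R")), L - 1L, replace = TRUE),
             sample(c("K", "R"), 1L))
    if (deamidated) {
      p <- sample(2:(L - 1L), 1L)
      res[p] <- paste0(sample(c("N", "Q"), 1L), "(UniMod:7)")
    }
    seqs <- paste(res, collapse = "")
    z <- sample(cfg$charges, 1L, prob = cfg$charge_probs)
    pmz <- precursor_mz(seqs, z)
    if (pmz >= windows[1L, "lo"] + 1 && pmz <= windows[nrow(windows), "hi"] - 1) {
      theo <- theoretical_fragment_mzs(seqs, 2L)  # singly charged b/y
      ok <- theo$index >= 2L & theo$mz >= 200 & theo$mz <= 1500
      if (sum(ok) >= 4L) {
        return(list(sequence = seqs, charge = z, precursor_mz = pmz,
                    theo = theo[ok, , drop = FALSE]))
      }
    }
  }
  stop("could not generate a peptide inside the isolation window scheme; ",
       "the window configuration is infeasible")
}

synth_peptide_set <- function(cfg, n, windows, deamidation_fraction = 0) {
  peps <- vector("list", n)
  seen <- character()
  n_deam <- round(n * deamidation_fraction)
  for (i in seq_len(n)) {
    repeat {
      p <- random_peptide(cfg, windows, deamidated = i <= n_deam)
      if (!(p$sequence %in% seen)) break
    }
    seen <- c(seen, p$sequence)
    nf <- min(sample(cfg$n_fragments[1L]:cfg$n_fragments[2L], 1L),
              nrow(p$theo))
    sel <- sort(sample(nrow(p$theo), nf))
    frag <- p$theo[sel, , drop = FALSE]
    frag$library_intensity <- round(stats::runif(nf, 50, 1000), 2)
    p$fragments <- frag
    p$normalized_rt <- round(stats::runif(1L, cfg$nrt_range[1L],
                                          cfg$nrt_range[2L]), 3)
    peps[[i]] <- p
  }
  peps
}

peptides_to_library <- function(peps, protein_ids) {
  entries <- lapply(seq_along(peps), function(i) {
    p <- peps[[i]]
    list(modified_sequence = p$sequence,
         peptide_sequence = gsub("\\(UniMod:[0-9]+\\)", "", p$sequence),
         precursor_mz = p$precursor_mz, precursor_charge = p$charge,
         normalized_rt = p$normalized_rt, protein_id = protein_ids[i],
         is_decoy = FALSE,
         fragments = data.frame(
           annotation = p$fragments$annotation, series = p$fragments$series,
           index = p$fragments$index, charge = p$fragments$charge,
           mz = p$fragments$mz,
           library_intensity = p$fragments$library_intensity,
           stringsAsFactors = FALSE))
  })
  new_speclib(entries)
}

#' Generate a synthetic DIA experiment
#'
#' @param cfg A \code{\link{synth_config}}.
#' @param dir Optional output directory; when given, the run
#'   (mzML/mzXML), the library TSV and the ground-truth TSV are written.
#' @param format Run file format when writing.
#' @param condition 1 or 2; under a two-condition configuration
#'   (\code{condition_ratios}), condition 2 multiplies each group's
#'   abundances by its fold change. Peptides, presence and base abundances
#'   are identical across conditions.
#' @return List with \code{library} (a \code{dia_speclib} of targets),
#'   \code{run} (in-memory \code{dia_run}), \code{truth} (data.frame) and
#'   \code{paths}.
#' @export
generate_experiment <- function(cfg, dir = NULL, format = c("mzml", "mzxml"),
                                condition = 1L) {
  format <- match.arg(format)
  windows <- synth_windows(cfg)
  n <- cfg$n_precursors

  base <- with_local_seed(cfg$seed, {
    peps <- synth_peptide_set(cfg, n, windows, cfg$deamidation_fraction)
    present <- logical(n)
    present[sample(n, round(n * cfg$fraction_present))] <- TRUE
    abundance <- stats::rlnorm(n, cfg$abundance_meanlog, cfg$abundance_sdlog)
    sigma <- cfg$peak_width_s * stats::runif(n, 0.8, 1.2)
    group <- if (is.null(cfg$condition_ratios)) rep(1L, n)
             else rep(seq_along(cfg$condition_ratios), length.out = n)
    n_intf <- round(cfg$interference_rate * n)
    intf <- if (n_intf > 0) synth_peptide_set(cfg, n_intf, windows) else list()
    intf_abund <- stats::rlnorm(max(n_intf, 0L), cfg$abundance_meanlog,
                                cfg$abundance_sdlog)
    intf_apex <- stats::runif(max(n_intf, 0L), 0,
                              cfg$n_cycles_total * cfg$cycle_time_s)
    intf_sigma <- cfg$peak_width_s * stats::runif(max(n_intf, 0L), 0.8, 1.2)
    list(peps = peps, present = present, abundance = abundance,
         sigma = sigma, group = group, intf = intf,
         intf_abund = intf_abund, intf_apex = intf_apex,
         intf_sigma = intf_sigma)
  })

  mult <- rep(1, n)
  if (!is.null(cfg$condition_ratios) && condition == 2L) {
    mult <- cfg$condition_ratios[base$group]
  }
  abundance <- base$abundance * mult
  apex_s <- cfg$rt_intercept + cfg$rt_slope *
    vapply(base$peps, `[[`, numeric(1), "normalized_rt")
  rt <- (seq_len(cfg$n_cycles_total) - 0.5) * cfg$cycle_time_s

  run <- with_local_seed(cfg$seed + 1000003L * as.integer(condition), {
    emit_run(cfg, windows, rt, base, abundance, apex_s)
  })

  protein_ids <- paste0("PROT_", rep(seq_len(max(1L, ceiling(n / 3))),
                                     each = 3L, length.out = n))
  lib <- peptides_to_library(base$peps, protein_ids)
  truth <- data.frame(
    modified_sequence = vapply(base$peps, `[[`, character(1), "sequence"),
    precursor_charge = vapply(base$peps, `[[`, integer(1), "charge"),
    precursor_mz = vapply(base$peps, `[[`, numeric(1), "precursor_mz"),
    normalized_rt = vapply(base$peps, `[[`, numeric(1), "normalized_rt"),
    present = base$present, apex_s = apex_s,
    apex_cycle = vapply(apex_s, function(a) which.min(abs(rt - a)), integer(1)),
    abundance = abundance, group = base$group,
    protein_id = protein_ids, stringsAsFactors = FALSE)

  paths <- list()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (format == "mzml") ".mzML" else ".mzXML"
    paths$run <- file.path(dir, paste0("run_c", condition, ext))
    paths$library <- file.path(dir, "library.tsv")
    paths$truth <- file.path(dir, paste0("truth_c", condition, ".tsv"))
    write_run(run, paths$run, format)
    write_library(lib, paths$library)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(library = lib, run = run, truth = truth, paths = paths, config = cfg)
}

# Emit all peaks and assemble the in-memory run.
emit_run <- function(cfg, windows, rt, base, abundance, apex_s) {
  n_cyc <- length(rt)
  species <- list()
  add_species <- function(pep, abund, apex, sigma) {
    shape <- exp(-(rt - apex)^2 / (2 * sigma^2))
    cyc <- which(shape > 0.01)
    if (!length(cyc)) return(NULL)
    sh <- shape[cyc]
    z <- pep$charge
    w <- which(windows[, "lo"] <= pep$precursor_mz &
               pep$precursor_mz <= windows[, "hi"])[1L]
    iso <- cfg$isotope_model
    ms1_mz <- pep$precursor_mz + (seq_along(iso) - 1L) * ISOTOPE_DELTA / z
    fr <- pep$fragments
    rel <- fr$library_intensity / 1000
    f_mz <- c(fr$mz, fr$mz + ISOTOPE_DELTA / fr$charge)
    f_rel <- c(rel, rel * cfg$ms2_isotope_ratio)
    list(cyc = rep(cyc, times = length(iso) + length(f_mz)),
         slot = rep(c(rep(0L, length(iso)), rep(w, length(f_mz))),
                    each = length(cyc)),
         mz = rep(c(ms1_mz, f_mz), each = length(cyc)),
         int = as.vector(outer(sh, abund * c(iso, f_rel))))
  }
  k <- 0L
  for (i in which(base$present)) {
    k <- k + 1L
    species[[k]] <- add_species(base$peps[[i]], abundance[i], apex_s[i],
                                base$sigma[i])
  }
  for (j in seq_along(base$intf)) {
    k <- k + 1L
    species[[k]] <- add_species(base$intf[[j]], base$intf_abund[j],
                                base$intf_apex[j], base$intf_sigma[j])
  }
  species <- Filter(Negate(is.null), species)
  cyc <- unlist(lapply(species, `[[`, "cyc"), use.names = FALSE)
  slot <- unlist(lapply(species, `[[`, "slot"), use.names = FALSE)
  mz <- unlist(lapply(species, `[[`, "mz"), use.names = FALSE)
  int <- unlist(lapply(species, `[[`, "int"), use.names = FALSE)

  # sparse noise floor over every spectrum
  if (cfg$noise_peaks > 0 && cfg$noise_floor > 0) {
    n_spec <- n_cyc * (nrow(windows) + 1L)
    n_noise <- stats::rpois(n_spec, cfg$noise_peaks)
    tot <- sum(n_noise)
    spec_cyc <- rep(rep(seq_len(n_cyc), each = nrow(windows) + 1L), n_noise)
    spec_slot <- rep(rep(0L:nrow(windows), times = n_cyc), n_noise)
    noise_mz <- ifelse(spec_slot == 0L,
                       stats::runif(tot, cfg$window_range[1L], cfg$window_range[2L]),
                       stats::runif(tot, 100, 1500))
    cyc <- c(cyc, spec_cyc); slot <- c(slot, spec_slot)
    mz <- c(mz, noise_mz)
    int <- c(int, stats::rexp(tot, rate = 1 / cfg$noise_floor))
  }
  if (cfg$mz_jitter_ppm > 0) {
    mz <- mz * (1 + stats::rnorm(length(mz)) * cfg$mz_jitter_ppm * 1e-6)
  }

  key <- (cyc - 1L) * (nrow(windows) + 1L) + slot + 1L
  parts <- split(seq_along(key), key)
  ms1 <- rep(list(EMPTY_SPECTRUM), n_cyc)
  ms2 <- lapply(seq_len(nrow(windows)), function(w) rep(list(EMPTY_SPECTRUM), n_cyc))
  for (nm in names(parts)) {
    idx <- parts[[nm]]
    kk <- as.integer(nm) - 1L
    cy <- kk %/% (nrow(windows) + 1L) + 1L
    sl <- kk %% (nrow(windows) + 1L)
    sp <- new_spectrum(mz[idx], int[idx])
    if (sl == 0L) ms1[[cy]] <- sp else ms2[[sl]][[cy]] <- sp
  }
  new_run(rt, windows, ms1, ms2, source = "synthetic")
}

#' Build a labeled RSM training set from a synthetic experiment
#'
#' Balanced target/decoy RSMs assembled with the real matrix-assembly code
#' (no shortcut synthesis): targets are present precursors windowed at
#' their true apex (+/- 1 cycle of jitter), decoys are sequence-level
#' decoys of the same precursors windowed at the same locations.
#'
#' @param experiment Output of \code{\link{generate_experiment}} (or a
#'   \code{synth_config}, which is generated first).
#' @param n_rsms Total number of RSMs (half per class).
#' @param seed Integer seed.
#' @param params \code{\link{rsm_params}}.
#' @param decoy_method Decoy generation method.
#' @return List with \code{rsms} (normalized matrices), \code{labels}
#'   (1 = target, 0 = decoy) and \code{groups} (precursor identifiers).
#' @export
generate_rsm_training_set <- function(experiment, n_rsms = 2000L, seed = 1L,
                                      params = rsm_params(),
                                      decoy_method = "shuffle") {
  if (inherits(experiment, "synth_config")) {
    experiment <- generate_experiment(experiment)
  }
  run <- experiment$run
  truth <- experiment$truth
  lib <- experiment$library
  n_half <- n_rsms %/% 2L
  present_idx <- which(truth$present)
  with_local_seed(seed, {
    pick <- sample(present_idx, n_half, replace = n_half > length(present_idx))
    jit <- sample(-1:1, n_half, replace = TRUE)
    forbidden <- vapply(lib$entries, `[[`, character(1), "modified_sequence")
    rsms <- vector("list", 2L * n_half)
    labels <- rep(c(1, 0), each = n_half)
    groups <- character(2L * n_half)
    for (k in seq_len(n_half)) {
      i <- pick[k]
      center <- truth$apex_cycle[i] + jit[k]
      rsms[[k]] <- normalize_rsm(
        assemble_rsm(run, lib$entries[[i]], center_cycle = center,
                     params = params))$matrix
      groups[k] <- paste0("T:", truth$modified_sequence[i])
      dec <- generate_decoy(lib$entries[[i]], method = decoy_method,
                            seed = seed, forbidden = forbidden)
      if (is.null(dec)) dec <- generate_decoy(lib$entries[[i]], "reverse")
      rsms[[n_half + k]] <- normalize_rsm(
        assemble_rsm(run, dec, center_cycle = center,
                     params = params))$matrix
      groups[n_half + k] <- paste0("D:", truth$modified_sequence[i])
    }
    list(rsms = rsms, labels = labels, groups = groups)
  })
}
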