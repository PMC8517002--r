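# End-to-end peptide-centric analysis of one DIA run.

#' Analyze a DIA run against a spectral library
#'
#' Runs the full peptide-centric workflow: decoy generation (when the
#' library has none), RT anchor selection and calibration, candidate
#' enumeration with test-time augmentation, positive-unlabeled rescoring,
#' target-decoy FDR estimation, and correlation-weighted quantification of
#' passing precursors with top-three protein rollup.
#'
#' @param run A \code{dia_run}.
#' @param lib A \code{dia_speclib} (decoys are generated with
#'   \code{decoy_method} if absent).
#' @param model A trained \code{dia_rep_model}.
#' @param decoy_method Decoy generation method.
#' @param rt_kind "linear" or "lowess" RT calibration.
#' @param classifier "xgboost" or "random_forest".
#' @param fdr Precursor q-value threshold for the pass flag and for
#'   quantification.
#' @param rt_half_window Candidate window half-width in cycles.
#' @param dds_threshold dds threshold for test-time augmentation.
#' @param n_rt_anchors Precursors sampled for RT calibration.
#' @param anchor_dds_min dds acceptance threshold for anchors.
#' @param params \code{\link{rsm_params}}.
#' @param cross_fit Two-fold cross-scoring for the PU classifier.
#' @param quantify Compute precursor/protein quantities.
#' @param seed Integer seed controlling every stochastic stage.
#' @param verbose Progress messages.
#' @return A \code{dia_results} object: \code{results} (one row per
#'   precursor, decoys included), \code{proteins}, \code{rt_model},
#'   \code{settings}.
#' @export
dia_pipeline <- function(run, lib, model, decoy_method = "shuffle",
                         rt_kind = "linear",
                         classifier = c("xgboost", "random_forest"),
                         fdr = 0.01, rt_half_window = 25L,
                         dds_threshold = 0.5, n_rt_anchors = 500L,
                         anchor_dds_min = 0.5, params = rsm_params(),
                         cross_fit = TRUE, quantify = TRUE, seed = 1L,
                         verbose = FALSE) {
  classifier <- match.arg(classifier)
  stopifnot(fdr > 0, fdr < 1)
  say <- function(...) if (verbose) message(...)

  has_decoys <- any(vapply(lib$entries, `[[`, logical(1), "is_decoy"))
  if (!has_decoys) {
    say("generating decoys (", decoy_method, ")")
    lib <- generate_decoy_library(lib, method = decoy_method, seed = seed)
  }

  say("selecting RT anchors")
  anchors <- select_anchors(run, lib, model, n_sample = n_rt_anchors,
                            seed = seed, dds_min = anchor_dds_min,
                            params = params)
  rt_model <- fit_rt_model(anchors, kind = rt_kind, seed = seed)
  say("RT model: ", paste(utils::capture.output(print(rt_model)), collapse = ""))

  say("enumerating candidates")
  candidates <- enumerate_all_candidates(run, lib, rt_model, model,
                                         rt_half_window = rt_half_window,
                                         dds_threshold = dds_threshold,
                                         params = params, verbose = verbose)
  say("training PU classifier (", classifier, ")")
  clf <- train_pu_classifier(candidates, model_type = classifier,
                             seed = seed, cross_fit = cross_fit)
  scored <- score_and_select(candidates, clf)
  scored <- estimate_fdr(scored, level = "precursor")
  scored$passes_fdr <- !scored$is_decoy & scored$q_value <= fdr

  if (quantify) {
    say("quantifying")
    scored$quantity <- NA_real_
    ekey <- vapply(lib$entries, entry_key, character(1))
    todo <- which(scored$passes_fdr | !scored$is_decoy)
    for (i in todo) {
      key <- paste(scored$modified_sequence[i], scored$precursor_charge[i],
                   as.integer(scored$is_decoy[i]), sep = "|")
      e <- lib$entries[[match(key, ekey)]]
      rsm <- assemble_rsm(run, e, center_cycle = scored$center_cycle[i],
                          params = params)
      scored$quantity[i] <- suppressWarnings(quantify_precursor(rsm)$Q)
    }
  }

  proteins <- NULL
  pass <- scored[scored$passes_fdr, , drop = FALSE]
  prot_fdr <- estimate_fdr(scored, level = "protein")
  if (quantify && nrow(pass)) {
    qs <- split(pass$quantity, pass$protein_id)
    proteins <- data.frame(protein_id = names(qs),
                           n_precursors = lengths(qs),
                           quantity = vapply(qs, quantify_protein, numeric(1)),
                           stringsAsFactors = FALSE)
    proteins$q_value <- prot_fdr$q_value[match(proteins$protein_id,
                                               prot_fdr$protein_id)]
    rownames(proteins) <- NULL
  }

  structure(list(results = scored, proteins = proteins,
                 protein_fdr = prot_fdr, rt_model = rt_model,
                 anchors = anchors,
                 settings = list(decoy_method = decoy_method,
                                 rt_kind = rt_kind, classifier = classifier,
                                 fdr = fdr, rt_half_window = rt_half_window,
                                 dds_threshold = dds_threshold,
                                 n_rt_anchors = n_rt_anchors,
                                 cross_fit = cross_fit, seed = seed,
                                 params = params)),
            class = "dia_results")
}

#' @export
print.dia_results <- function(x, ...) {
  r <- x$results
  cat("<dia_results> ", sum(!r$is_decoy), " targets, ", sum(r$is_decoy),
      " decoys scored\n", sep = "")
  cat("  ", sum(r$passes_fdr), " precursors pass q <= ",
      x$settings$fdr, "\n", sep = "")
  if (!is.null(x$proteins)) {
    cat("  ", nrow(x$proteins), " proteins quantified\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.dia_results <- function(object, ...) {
  r <- object$results
  tg <- r[!r$is_decoy, , drop = FALSE]
  out <- list(n_targets = nrow(tg), n_decoys = sum(r$is_decoy),
              n_pass = sum(r$passes_fdr),
              q_quantiles = stats::quantile(tg$q_value, c(0.01, 0.05, 0.1,
                                                          0.5, 0.9)),
              settings = object$settings)
  class(out) <- "summary.dia_results"
  out
}

#' @export
print.summary.dia_results <- function(x, ...) {
  cat("DIA analysis: ", x$n_targets, " targets / ", x$n_decoys,
      " decoys; ", x$n_pass, " pass FDR\n", sep = "")
  print(round(x$q_quantiles, 4))
  invisible(x)
}

#' Write result tables as TSV
#'
#' @param res A \code{dia_results}.
#' @param dir Output directory.
#' @param keep_decoys Include decoy rows in the precursor table.
#' @export
write_results <- function(res, dir, keep_decoys = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- res$results
  if (!keep_decoys) r <- r[!r$is_decoy, , drop = FALSE]
  cols <- c("modified_sequence", "precursor_charge", "protein_id",
            "is_decoy", "rt_s", "dds", "discriminant_score", "q_value",
            "passes_fdr", if ("quantity" %in% names(r)) "quantity")
  utils::write.table(r[, cols], file.path(dir, "precursors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$proteins)) {
    utils::write.table(res$proteins, file.path(dir, "proteins.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
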