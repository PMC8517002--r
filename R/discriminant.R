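# Positive-unlabeled rescoring and target-decoy FDR control.
#
# Candidate peak groups are enumerated with test-time augmentation: every
# RSM within a window around the predicted RT whose dds clears a threshold
# becomes a candidate (with a max-dds fallback so every precursor stays
# scoreable). A run-specific nonlinear classifier is trained with decoys
# as confirmed negatives and targets as the unlabeled class, over feature
# vectors combining the dds, the 16 deep representation features and
# auxiliary features (precursor m/z and charge, peptide length, RT
# deviation, library-block intensity). The best-scoring candidate per
# precursor enters FDR estimation.

CANDIDATE_FEATURES <- c("dds", paste0("deep", 1:16), "precursor_mz",
                        "precursor_charge", "peptide_length", "rt_deviation",
                        "log_library_intensity", "n_nonzero_library")

#' Enumerate candidate peak groups for one precursor
#'
#' @param run A \code{dia_run}.
#' @param entry Library entry (target or decoy).
#' @param rt_model Fitted \code{dia_rt_model}.
#' @param model Trained \code{dia_rep_model}.
#' @param rt_half_window Half-width (cycles) of the candidate window
#'   around the predicted RT.
#' @param dds_threshold Candidates must reach this dds; if none do, the
#'   single max-dds location is kept as a fallback.
#' @param params \code{\link{rsm_params}}.
#' @return data.frame with one row per candidate: identification columns,
#'   \code{center_cycle}, \code{dds}, deep feature columns
#'   \code{deep1..deep16} and the auxiliary features.
#' @export
enumerate_candidates <- function(run, entry, rt_model, model,
                                 rt_half_window = 25L, dds_threshold = 0.5,
                                 params = rsm_params()) {
  pred_s <- predict(rt_model, entry$normalized_rt)
  if (pred_s < run$rt[1L] - rt_half_window * stats::median(diff(run$rt)) ||
      pred_s > run$rt[n_cycles(run)] + rt_half_window * stats::median(diff(run$rt))) {
    message("predicted RT ", round(pred_s, 1), " s outside run for '",
            entry$modified_sequence, "'")
    return(NULL)
  }
  center0 <- rt_to_cycle(run, pred_s)
  centers <- max(1L, center0 - rt_half_window):min(n_cycles(run),
                                                   center0 + rt_half_window)
  bundle <- precursor_xic_bundle(run, entry, params)
  sc <- scan_dds(bundle, centers, model, params, return_features = TRUE)
  keep <- which(sc$dds >= dds_threshold)
  if (length(keep) == 0L) keep <- which.max(sc$dds)
  feats <- sc$features[keep, , drop = FALSE]
  colnames(feats) <- paste0("deep", seq_len(ncol(feats)))
  pep_len <- nrow(parse_modified_sequence(entry$modified_sequence))
  cbind(
    data.frame(modified_sequence = entry$modified_sequence,
               precursor_charge = entry$precursor_charge,
               protein_id = entry$protein_id, is_decoy = entry$is_decoy,
               center_cycle = centers[keep], rt_s = run$rt[centers[keep]],
               dds = sc$dds[keep], stringsAsFactors = FALSE),
    as.data.frame(feats),
    data.frame(precursor_mz = entry$precursor_mz,
               peptide_length = pep_len,
               rt_deviation = abs(centers[keep] - center0),
               log_library_intensity = log1p(sc$lib_sum[keep]),
               n_nonzero_library = sc$lib_nnz[keep]))
}

#' Enumerate candidates for every precursor in a library
#'
#' @inheritParams enumerate_candidates
#' @param lib A \code{dia_speclib} (targets and decoys).
#' @param verbose Report progress.
#' @return One data.frame of candidates for all precursors.
#' @export
enumerate_all_candidates <- function(run, lib, rt_model, model,
                                     rt_half_window = 25L,
                                     dds_threshold = 0.5,
                                     params = rsm_params(), verbose = FALSE) {
  entries <- lib$entries
  dt <- stats::median(diff(run$rt))
  n_cyc <- n_cycles(run)
  pred_s <- predict(rt_model,
                    vapply(entries, `[[`, numeric(1), "normalized_rt"))
  in_run <- pred_s >= run$rt[1L] - rt_half_window * dt &
            pred_s <= run$rt[n_cyc] + rt_half_window * dt
  if (any(!in_run)) {
    message(sum(!in_run), " precursor(s) with predicted RT outside the run")
  }
  keep_e <- which(in_run)
  if (!length(keep_e)) return(NULL)
  center0 <- rt_to_cycle(run, pred_s[keep_e])
  centers_list <- lapply(seq_along(keep_e), function(k) {
    max(1L, center0[k] - rt_half_window):min(n_cyc, center0[k] + rt_half_window)
  })
  scans <- scan_entries(run, entries[keep_e], centers_list, model, params,
                        return_features = TRUE)
  rows <- vector("list", length(keep_e))
  for (k in seq_along(keep_e)) {
    e <- entries[[keep_e[k]]]
    sc <- scans[[k]]
    centers <- centers_list[[k]]
    sel <- which(sc$dds >= dds_threshold)
    if (length(sel) == 0L) sel <- which.max(sc$dds)
    feats <- sc$features[sel, , drop = FALSE]
    colnames(feats) <- paste0("deep", seq_len(ncol(feats)))
    rows[[k]] <- cbind(
      data.frame(modified_sequence = e$modified_sequence,
                 precursor_charge = e$precursor_charge,
                 protein_id = e$protein_id, is_decoy = e$is_decoy,
                 center_cycle = centers[sel], rt_s = run$rt[centers[sel]],
                 dds = sc$dds[sel], stringsAsFactors = FALSE),
      as.data.frame(feats),
      data.frame(precursor_mz = e$precursor_mz,
                 peptide_length = nrow(parse_modified_sequence(e$modified_sequence)),
                 rt_deviation = abs(centers[sel] - center0[k]),
                 log_library_intensity = log1p(sc$lib_sum[sel]),
                 n_nonzero_library = sc$lib_nnz[sel]))
    if (verbose && k %% 1000L == 0L) {
      message("  candidates: ", k, "/", length(keep_e), " precursors")
    }
  }
  do.call(rbind, rows)
}

candidate_feature_matrix <- function(candidates) {
  as.matrix(candidates[, CANDIDATE_FEATURES])
}

#' Train the run-specific PU classifier
#'
#' Binary classifier between confirmed decoys (label 0) and unlabeled
#' targets (label 1) over all candidate feature vectors. XGBoost uses tree
#' depth 6; the random forest uses depth 12 with 200 trees. With
#' \code{cross_fit = TRUE} (the default), candidates are split into two
#' folds by precursor and each fold is scored by the classifier trained on
#' the other, so no candidate is scored by a model that saw it in
#' training.
#'
#' @param candidates Candidate data.frame from
#'   \code{\link{enumerate_all_candidates}} (must contain both targets and
#'   decoys).
#' @param model_type "xgboost" or "random_forest".
#' @param seed Integer seed.
#' @param nrounds Boosting rounds (xgboost).
#' @param cross_fit Use the two-fold cross-scoring scheme.
#' @param features Feature columns to train on (defaults to all; subset
#'   for ablation studies, e.g. auxiliary features only).
#' @return A \code{dia_pu_classifier}.
#' @export
train_pu_classifier <- function(candidates,
                               model_type = c("xgboost", "random_forest"),
                               seed = 1L, nrounds = 100L, cross_fit = TRUE,
                               features = CANDIDATE_FEATURES) {
  model_type <- match.arg(model_type)
  if (all(candidates$is_decoy)) stop("no target candidates to train on")
  if (!any(candidates$is_decoy)) {
    stop("no decoy candidates: cannot calibrate the classifier")
  }
  x <- as.matrix(candidates[, features, drop = FALSE])
  y <- as.numeric(!candidates$is_decoy)
  prec <- paste(candidates$modified_sequence, candidates$precursor_charge,
                candidates$is_decoy)
  fold_of <- NULL
  if (cross_fit) {
    u <- unique(prec)
    half <- with_local_seed(seed, sample(length(u)) %% 2L + 1L)
    fold_of <- stats::setNames(half, u)
  }
  fit_one <- function(idx, sd_off) {
    if (model_type == "xgboost") {
      dtrain <- xgboost::xgb.DMatrix(x[idx, , drop = FALSE], label = y[idx])
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6,
                      eta = 0.1, nthread = 1, seed = seed + sd_off),
        data = dtrain, nrounds = nrounds, verbose = 0)
    } else {
      df <- data.frame(y = factor(y[idx]), x[idx, , drop = FALSE])
      ranger::ranger(y ~ ., data = df, num.trees = 200, max.depth = 12,
                     probability = TRUE, seed = seed + sd_off,
                     num.threads = 1)
    }
  }
  models <- if (cross_fit) {
    lapply(1:2, function(f) fit_one(which(fold_of[prec] != f), f))
  } else {
    list(fit_one(seq_len(nrow(x)), 0L))
  }
  structure(list(models = models, model_type = model_type,
                 fold_of = fold_of, features = features,
                 seed = seed),
            class = "dia_pu_classifier")
}

#' @export
print.dia_pu_classifier <- function(x, ...) {
  cat("<dia_pu_classifier> ", x$model_type,
      if (length(x$models) > 1L) " (2-fold cross-scoring)" else "",
      ", ", length(x$features), " features\n", sep = "")
  invisible(x)
}

classifier_scores <- function(classifier, candidates) {
  x <- as.matrix(candidates[, classifier$features, drop = FALSE])
  score_with <- function(model, xx) {
    if (classifier$model_type == "xgboost") {
      predict(model, xgboost::xgb.DMatrix(xx))
    } else {
      predict(model, data.frame(xx), num.threads = 1)$predictions[, "1"]
    }
  }
  if (is.null(classifier$fold_of)) {
    return(score_with(classifier$models[[1L]], x))
  }
  prec <- paste(candidates$modified_sequence, candidates$precursor_charge,
                candidates$is_decoy)
  fold <- classifier$fold_of[prec]
  fold[is.na(fold)] <- 1L  # unseen precursors: either model is unbiased
  out <- numeric(nrow(x))
  for (f in 1:2) {
    idx <- which(fold == f)
    if (length(idx)) out[idx] <- score_with(classifier$models[[f]],
                                            x[idx, , drop = FALSE])
  }
  out
}

#' Score candidates and keep the best peak group per precursor
#'
#' Ties are broken by smaller RT deviation from the prediction, then by
#' earlier cycle. Decoys are retained alongside targets (they are needed
#' for FDR estimation).
#'
#' @param candidates Candidate data.frame.
#' @param classifier A \code{dia_pu_classifier}.
#' @return A \code{dia_scored} data.frame: one row per precursor with its
#'   best candidate and \code{discriminant_score}.
#' @export
score_and_select <- function(candidates, classifier) {
  candidates$discriminant_score <- classifier_scores(classifier, candidates)
  select_best_candidates(candidates)
}

# Max-score candidate per precursor; ties resolved by smaller RT
# deviation, then earlier cycle.
select_best_candidates <- function(candidates) {
  ord <- order(candidates$modified_sequence, candidates$precursor_charge,
               candidates$is_decoy, -candidates$discriminant_score,
               candidates$rt_deviation, candidates$center_cycle)
  cand <- candidates[ord, , drop = FALSE]
  key <- paste(cand$modified_sequence, cand$precursor_charge, cand$is_decoy)
  best <- cand[!duplicated(key), , drop = FALSE]
  rownames(best) <- NULL
  class(best) <- c("dia_scored", "data.frame")
  best
}

#' Estimate FDR and q-values by target-decoy competition
#'
#' At a cutoff c, FDR(c) = #\{decoys with score >= c\} / max(1, #\{targets
#' with score >= c\}). The q-value of a result is the minimum FDR over all
#' cutoffs at or below its score (monotonized). Protein-level estimation
#' groups results by protein, takes the maximal member score per protein,
#' and applies the same estimator.
#'
#' A library contains one decoy per target, but only the absent fraction
#' of targets can produce false identifications, so the raw decoy count
#' overstates the false-target pool by the null proportion pi0. The
#' default corrects for this with a Storey-type estimate: the ratio of
#' targets to decoys in the score region below the 90th percentile of the
#' decoy distribution, where true identifications are rare. \code{pi0 = 1}
#' gives the plain (conservative) decoys/targets estimator.
#'
#' @param results A \code{dia_scored} data.frame (targets and decoys).
#' @param level "precursor" or "protein".
#' @param pi0 "auto" (estimate the null proportion), or a number in
#'   (0, 1].
#' @return For precursor level: the input with a \code{q_value} column.
#'   For protein level: a data.frame of proteins with scores and q-values.
#' @export
estimate_fdr <- function(results, level = c("precursor", "protein"),
                         pi0 = "auto") {
  level <- match.arg(level)
  if (!any(!results$is_decoy)) stop("no target results; cannot estimate FDR")
  if (level == "protein") {
    key <- results$protein_id
    agg <- do.call(rbind, lapply(split(seq_len(nrow(results)), key),
      function(idx) {
        data.frame(protein_id = results$protein_id[idx[1L]],
                   is_decoy = results$is_decoy[idx[1L]],
                   discriminant_score = max(results$discriminant_score[idx]),
                   n_precursors = length(idx), stringsAsFactors = FALSE)
      }))
    rownames(agg) <- NULL
    results <- agg
  }
  if (identical(pi0, "auto")) {
    # null region: below the 90th percentile of decoy scores — nearly the
    # whole decoy null, while still under genuine identifications (any
    # leakage of true positives inflates pi0, i.e. errs conservative)
    s0 <- stats::quantile(results$discriminant_score[results$is_decoy], 0.9)
    n_t_low <- sum(!results$is_decoy & results$discriminant_score <= s0)
    n_d_low <- sum(results$is_decoy & results$discriminant_score <= s0)
    pi0 <- min(1, max(0.01, n_t_low / max(1L, n_d_low)))
  }
  stopifnot(is.numeric(pi0), pi0 > 0, pi0 <= 1)
  ord <- order(-results$discriminant_score)
  dec <- results$is_decoy[ord]
  fdr <- pi0 * cumsum(dec) / pmax(1, cumsum(!dec))
  # equal scores share the FDR of the last tied element
  s <- results$discriminant_score[ord]
  for (i in rev(seq_along(s)[-length(s)])) {
    if (s[i] == s[i + 1L]) fdr[i] <- fdr[i + 1L]
  }
  q <- rev(cummin(rev(fdr)))
  results$q_value[ord] <- q
  results
}
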