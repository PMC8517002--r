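# Retention-time calibration: library normalized RT -> run RT.
#
# A random sample of endogenous (target) precursors is scanned across the
# whole gradient; the cycle with the maximal deep discriminant score is the
# anchor for each. A robust regression then maps normalized RT to run
# seconds: RANSAC for the linear model, LOWESS with a residual-based
# outlier pass for the nonlinear one.

# dds of one precursor's RSMs at many candidate centers (batched forward).
scan_dds <- function(bundle, centers, model, params,
                     return_features = FALSE) {
  n <- length(centers)
  arr <- array(0, dim = c(n, sum(rsm_layout(params)), params$n_cycles))
  lib_sum <- numeric(n); lib_nnz <- numeric(n)
  nL <- params$sizes[["library_r"]]
  for (k in seq_len(n)) {
    m <- rsm_matrix_at(bundle, centers[k], params)$matrix
    lib_block <- m[seq_len(min(nL, nrow(m))), , drop = FALSE]
    lib_sum[k] <- sum(lib_block)
    lib_nnz[k] <- sum(rowSums(lib_block) > 0)
    arr[k, , ] <- normalize_rsm(m)
  }
  out <- predict(model, arr, type = if (return_features) "both" else "dds")
  if (return_features) {
    list(dds = out$dds, features = out$features, lib_sum = lib_sum,
         lib_nnz = lib_nnz)
  } else {
    list(dds = out, lib_sum = lib_sum, lib_nnz = lib_nnz)
  }
}

# Batched scan over many precursors: bundles are built per entry, windows
# are accumulated into chunks of ~chunk_windows RSMs, and the model runs
# one forward pass per chunk. Returns one scan_dds-style result per entry.
scan_entries <- function(run, entries, centers_list, model, params,
                         return_features = FALSE, chunk_windows = 4096L) {
  n_rows <- sum(rsm_layout(params))
  nL <- params$sizes[["library_r"]]
  n <- length(entries)
  res <- vector("list", n)
  i <- 1L
  while (i <= n) {
    j <- i
    tot <- length(centers_list[[i]])
    while (j < n && tot + length(centers_list[[j + 1L]]) <= chunk_windows) {
      j <- j + 1L
      tot <- tot + length(centers_list[[j]])
    }
    arr <- array(0, dim = c(tot, n_rows, params$n_cycles))
    lib_sum <- numeric(tot); lib_nnz <- numeric(tot)
    pos <- 0L
    for (k in i:j) {
      bundle <- precursor_xic_bundle(run, entries[[k]], params)
      for (cc in centers_list[[k]]) {
        pos <- pos + 1L
        m <- rsm_matrix_at(bundle, cc, params)$matrix
        lb <- m[seq_len(min(nL, n_rows)), , drop = FALSE]
        lib_sum[pos] <- sum(lb)
        lib_nnz[pos] <- sum(rowSums(lb) > 0)
        mx <- max(m)
        arr[pos, , ] <- if (mx > 0) m / mx else m
      }
    }
    pred <- predict(model, arr, type = if (return_features) "both" else "dds")
    pos <- 0L
    for (k in i:j) {
      nk <- length(centers_list[[k]])
      idx <- pos + seq_len(nk)
      pos <- pos + nk
      res[[k]] <- list(
        dds = if (return_features) pred$dds[idx] else pred[idx],
        features = if (return_features) pred$features[idx, , drop = FALSE],
        lib_sum = lib_sum[idx], lib_nnz = lib_nnz[idx])
    }
    i <- j + 1L
  }
  res
}

#' Select RT anchors by scanning the gradient
#'
#' Randomly samples target precursors from the library, assembles their
#' RSMs at every cycle of the gradient, and keeps the cycle with the
#' maximal dds as each precursor's anchor. Anchors with dds below
#' \code{dds_min} are discarded as likely-absent precursors.
#'
#' @param run A \code{dia_run}.
#' @param lib A \code{dia_speclib}.
#' @param model A trained \code{dia_rep_model}.
#' @param n_sample Number of precursors to sample (clipped with a warning
#'   when the library is smaller).
#' @param seed Integer seed.
#' @param dds_min Anchor acceptance threshold on dds.
#' @param params \code{\link{rsm_params}}.
#' @return data.frame with one row per accepted anchor:
#'   \code{normalized_rt}, \code{best_cycle}, \code{best_rt_s}, \code{dds}.
#' @export
select_anchors <- function(run, lib, model, n_sample = 500L, seed = 1L,
                           dds_min = 0.5, params = rsm_params()) {
  targets <- which(!vapply(lib$entries, `[[`, logical(1), "is_decoy"))
  if (n_sample > length(targets)) {
    warning("n_sample (", n_sample, ") exceeds the number of targets (",
            length(targets), "); using all targets")
    n_sample <- length(targets)
  }
  pick <- with_local_seed(seed, sample(targets, n_sample))
  centers <- seq_len(n_cycles(run))
  entries <- lib$entries[pick]
  scans <- scan_entries(run, entries, rep(list(centers), length(pick)),
                        model, params)
  best <- vapply(scans, function(s) which.max(s$dds), integer(1))
  out <- data.frame(
    modified_sequence = vapply(entries, `[[`, character(1), "modified_sequence"),
    precursor_charge = vapply(entries, `[[`, integer(1), "precursor_charge"),
    normalized_rt = vapply(entries, `[[`, numeric(1), "normalized_rt"),
    best_cycle = centers[best], best_rt_s = run$rt[centers[best]],
    dds = vapply(seq_along(scans), function(k) scans[[k]]$dds[best[k]],
                 numeric(1)),
    stringsAsFactors = FALSE)
  out[out$dds >= dds_min, , drop = FALSE]
}

ols_line <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  c(intercept = fit$coefficients[[1L]], slope = fit$coefficients[[2L]])
}

#' Fit an RT calibration model to anchors
#'
#' Linear: RANSAC (minimal two-point samples, inlier threshold 2.5 x MAD
#' of a preliminary least-squares fit, 100 iterations, final ordinary
#' least-squares refit on the inlier consensus set). Nonlinear: LOWESS
#' (span 0.3, 2 robustness iterations) with points beyond 3 x MAD of the
#' smoothed curve removed, then refit.
#'
#' @param anchors data.frame with \code{normalized_rt} and
#'   \code{best_rt_s} columns (as from \code{\link{select_anchors}}).
#' @param kind "linear" or "lowess".
#' @param seed Seed for RANSAC sampling.
#' @param n_iterations RANSAC iterations.
#' @param lowess_span LOWESS smoother span.
#' @return A \code{dia_rt_model} with \code{predict} and \code{coef}
#'   methods mapping normalized RT to run seconds.
#' @export
fit_rt_model <- function(anchors, kind = c("linear", "lowess"), seed = 1L,
                         n_iterations = 100L, lowess_span = 0.3) {
  kind <- match.arg(kind)
  x <- anchors$normalized_rt
  y <- anchors$best_rt_s
  min_n <- if (kind == "linear") 10L else 30L
  if (length(x) < min_n) {
    stop("too few anchors for kind='", kind, "': ", length(x),
         " (minimum ", min_n, ")")
  }
  if (kind == "linear") {
    prelim <- ols_line(x, y)
    resid <- y - prelim["intercept"] - prelim["slope"] * x
    thr <- 2.5 * stats::mad(resid)
    if (thr <= 0) thr <- 2.5 * stats::sd(resid) + 1e-9
    best_inliers <- NULL; best_n <- -1L; best_rss <- Inf
    with_local_seed(seed, {
      for (it in seq_len(n_iterations)) {
        s <- sample(length(x), 2L)
        if (x[s[1L]] == x[s[2L]]) next
        slope <- (y[s[2L]] - y[s[1L]]) / (x[s[2L]] - x[s[1L]])
        intercept <- y[s[1L]] - slope * x[s[1L]]
        r <- y - intercept - slope * x
        inl <- abs(r) <= thr
        rss <- sum(r[inl]^2)
        if (sum(inl) > best_n || (sum(inl) == best_n && rss < best_rss)) {
          best_n <- sum(inl); best_rss <- rss; best_inliers <- inl
        }
      }
    })
    if (is.null(best_inliers) || best_n < 2L) best_inliers <- rep(TRUE, length(x))
    # iterative refinement: refit on the consensus set, re-derive the
    # 2.5 x MAD threshold from the refit residuals, reselect inliers
    for (refine in 1:3) {
      cf <- ols_line(x[best_inliers], y[best_inliers])
      resid <- y - cf["intercept"] - cf["slope"] * x
      thr2 <- 2.5 * stats::mad(resid[best_inliers])
      if (thr2 <= 0) break
      new_inliers <- abs(resid) <= thr2
      if (identical(new_inliers, best_inliers)) break
      best_inliers <- new_inliers
    }
    cf <- ols_line(x[best_inliers], y[best_inliers])
    resid <- y - cf["intercept"] - cf["slope"] * x
    model <- list(kind = "linear", coefficients = cf, inliers = best_inliers,
                  sigma = stats::mad(resid[best_inliers]),
                  range = range(x), anchors = anchors)
  } else {
    sm <- stats::lowess(x, y, f = lowess_span, iter = 2L)
    fitted <- stats::approx(sm$x, sm$y, xout = x, rule = 2, ties = mean)$y
    resid <- y - fitted
    keep <- abs(resid) <= 3 * stats::mad(resid) + 1e-9
    sm <- stats::lowess(x[keep], y[keep], f = lowess_span, iter = 2L)
    fitted <- stats::approx(sm$x, sm$y, xout = x, rule = 2, ties = mean)$y
    model <- list(kind = "lowess", curve = sm, inliers = keep,
                  sigma = stats::mad((y - fitted)[keep]),
                  range = range(x[keep]), anchors = anchors)
  }
  structure(model, class = "dia_rt_model")
}

#' @export
print.dia_rt_model <- function(x, ...) {
  if (x$kind == "linear") {
    cat("<dia_rt_model> linear: run_s = ",
        round(x$coefficients[["slope"]], 4), " * nrt + ",
        round(x$coefficients[["intercept"]], 3), "; ",
        sum(x$inliers), "/", length(x$inliers), " inliers, sigma ",
        round(x$sigma, 2), " s\n", sep = "")
  } else {
    cat("<dia_rt_model> lowess over [", round(x$range[1L], 2), ", ",
        round(x$range[2L], 2), "]; ", sum(x$inliers), "/",
        length(x$inliers), " points kept, sigma ", round(x$sigma, 2),
        " s\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.dia_rt_model <- function(object, ...) {
  if (object$kind == "linear") object$coefficients else object$curve
}

#' Predict run RT (seconds) from library normalized RT
#'
#' Linear models extrapolate beyond the anchor range; LOWESS predictions
#' are clamped to the boundary values.
#'
#' @param object A \code{dia_rt_model}.
#' @param normalized_rt Numeric vector.
#' @param ... Unused.
#' @export
predict.dia_rt_model <- function(object, normalized_rt, ...) {
  if (object$kind == "linear") {
    object$coefficients[["intercept"]] +
      object$coefficients[["slope"]] * normalized_rt
  } else {
    stats::approx(object$curve$x, object$curve$y, xout = normalized_rt,
                  rule = 2, ties = mean)$y
  }
}

#' Map a run RT in seconds to the nearest cycle index
#' @param run A \code{dia_run}.
#' @param seconds Numeric vector of run times.
#' @export
rt_to_cycle <- function(run, seconds) {
  vapply(seconds, function(s) which.min(abs(run$rt - s)), integer(1))
}

#' Predict the run cycle of a library precursor
#'
#' @param model A fitted \code{dia_rt_model}.
#' @param normalized_rt Library RT value(s).
#' @param run A \code{dia_run} (for the seconds -> cycle mapping).
#' @export
predict_rt_cycle <- function(model, normalized_rt, run) {
  rt_to_cycle(run, predict(model, normalized_rt))
}
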