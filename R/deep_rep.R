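# Deep representation model.
#
# Two stacked LSTM layers (128 and 64 units, input dropout 0.4, recurrent
# dropout 0.3 applied Keras-style: one mask per sequence, shared across
# time steps) followed by two fully-connected layers (16 ReLU units, then a
# single sigmoid unit). The matrix is consumed along its cycle axis: one
# time step per acquisition cycle, with the XIC rows as the per-step
# feature vector. The 16-unit penultimate activations are the deep
# representation features; the sigmoid output is the deep discriminant
# score (dds). Trained with binary cross-entropy (targets = 1, decoys = 0)
# and Adam; implemented in vectorised base R with explicit
# backpropagation-through-time.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

orthogonal_gates <- function(h, gates = 4L) {
  do.call(cbind, lapply(seq_len(gates), function(g) {
    qr.Q(qr(matrix(stats::rnorm(h * h), h, h)))
  }))
}

new_lstm_layer <- function(in_dim, units) {
  b <- rep(0, 4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget-gate bias
  list(W = glorot(in_dim, 4L * units), U = orthogonal_gates(units), b = b,
       units = units, in_dim = in_dim)
}

#' Build an (untrained) deep representation model
#'
#' @param n_rows Number of XIC rows the model consumes per cycle.
#' @param n_cycles Sequence length (acquisition cycles).
#' @param units LSTM layer widths.
#' @param n_features Width of the penultimate fully-connected layer (the
#'   deep representation features).
#' @param dropout \code{c(input, recurrent)} dropout rates for both LSTM
#'   layers (train time only; inference is deterministic).
#' @param seed Integer seed for weight initialisation.
#' @return A \code{dia_rep_model}.
#' @export
build_rep_model <- function(n_rows = 170L, n_cycles = 12L,
                            units = c(128L, 64L), n_features = 16L,
                            dropout = c(0.4, 0.3), seed = 1L) {
  stopifnot(n_rows >= 1L, n_cycles >= 1L, length(units) == 2L)
  with_local_seed(seed, {
    model <- structure(list(
      l1 = new_lstm_layer(n_rows, units[1L]),
      l2 = new_lstm_layer(units[1L], units[2L]),
      fc1 = list(W = glorot(units[2L], n_features), b = rep(0, n_features)),
      fc2 = list(W = glorot(n_features, 1L), b = 0),
      n_rows = as.integer(n_rows), n_cycles = as.integer(n_cycles),
      n_features = as.integer(n_features), dropout = dropout,
      seed = as.integer(seed), trained = FALSE, history = NULL),
      class = "dia_rep_model")
    model
  })
}

#' @export
print.dia_rep_model <- function(x, ...) {
  cat("<dia_rep_model> LSTM(", x$l1$units, ") -> LSTM(", x$l2$units,
      ") -> FC(", x$n_features, ") -> FC(1), input ", x$n_rows, " x ",
      x$n_cycles, if (x$trained) ", trained" else ", untrained", "\n",
      sep = "")
  if (!is.null(x$history)) {
    cat("  final val loss: ",
        round(utils::tail(x$history$val_loss, 1L), 4), " after ",
        nrow(x$history), " epoch(s)\n", sep = "")
  }
  invisible(x)
}

# One LSTM layer over a batch. x_steps: list (length T) of B x D inputs.
# Masks are inverted-dropout masks (already scaled) or NULL.
lstm_forward <- function(layer, x_steps, mask_in = NULL, mask_rec = NULL,
                         keep_cache = FALSE) {
  H <- layer$units
  B <- nrow(x_steps[[1L]])
  Tn <- length(x_steps)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  bmat <- matrix(layer$b, B, 4L * H, byrow = TRUE)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  cache <- if (keep_cache) vector("list", Tn)
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xd <- if (is.null(mask_in)) x_steps[[t]] else x_steps[[t]] * mask_in
    hd <- if (is.null(mask_rec)) h else h * mask_rec
    z <- xd %*% layer$W + hd %*% layer$U + bmat
    i <- sigmoid(z[, ii, drop = FALSE])
    f <- sigmoid(z[, ff, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, oo, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    out[[t]] <- h
    if (keep_cache) {
      cache[[t]] <- list(xd = xd, hd = hd, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc)
    }
  }
  list(out = out, cache = cache)
}

# Backpropagation through time for one layer. d_out: list of B x H
# gradients w.r.t. the layer outputs (zero matrices where unused).
lstm_backward <- function(layer, cache, d_out, mask_in = NULL,
                          mask_rec = NULL) {
  H <- layer$units
  Tn <- length(cache)
  B <- nrow(d_out[[Tn]])
  dW <- layer$W * 0; dU <- layer$U * 0; db <- layer$b * 0
  d_x <- vector("list", Tn)
  dh <- d_out[[Tn]]; dc <- matrix(0, B, H)
  ii <- seq_len(H); ff <- H + ii; gg <- 2L * H + ii; oo <- 3L * H + ii
  dz <- matrix(0, B, 4L * H)
  for (t in seq(Tn, 1L)) {
    cc <- cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    dz[, ii] <- (dc * cc$g) * cc$i * (1 - cc$i)
    dz[, ff] <- (dc * cc$c_prev) * cc$f * (1 - cc$f)
    dz[, gg] <- (dc * cc$i) * (1 - cc$g^2)
    dz[, oo] <- do_ * cc$o * (1 - cc$o)
    dW <- dW + crossprod(cc$xd, dz)
    dU <- dU + crossprod(cc$hd, dz)
    db <- db + colSums(dz)
    dxd <- tcrossprod(dz, layer$W)
    d_x[[t]] <- if (is.null(mask_in)) dxd else dxd * mask_in
    dhd <- tcrossprod(dz, layer$U)
    dh_rec <- if (is.null(mask_rec)) dhd else dhd * mask_rec
    dh <- if (t > 1L) d_out[[t - 1L]] + dh_rec else dh_rec
    dc <- dc * cc$f
  }
  list(dW = dW, dU = dU, db = db, d_x = d_x)
}

# Full forward pass. x_arr: B x n_rows x n_cycles array.
rep_forward <- function(model, x_arr, masks = NULL, keep_cache = FALSE) {
  Tn <- dim(x_arr)[3L]
  x_steps <- lapply(seq_len(Tn), function(t)
    matrix(x_arr[, , t], nrow = dim(x_arr)[1L]))
  l1 <- lstm_forward(model$l1, x_steps,
                     if (is.null(masks)) NULL else masks$in1,
                     if (is.null(masks)) NULL else masks$rec1, keep_cache)
  l2 <- lstm_forward(model$l2, l1$out,
                     if (is.null(masks)) NULL else masks$in2,
                     if (is.null(masks)) NULL else masks$rec2, keep_cache)
  h_last <- l2$out[[Tn]]
  z1 <- sweep(h_last %*% model$fc1$W, 2L, model$fc1$b, "+")
  a1 <- pmax(z1, 0)
  z2 <- as.vector(a1 %*% model$fc2$W + model$fc2$b)
  p <- sigmoid(z2)
  list(p = p, features = a1, h_last = h_last,
       l1 = l1, l2 = l2, x_steps = if (keep_cache) x_steps)
}

# Gradients of mean binary cross-entropy w.r.t. all parameters.
rep_backward <- function(model, fwd, y, masks) {
  B <- length(y)
  Tn <- model$n_cycles
  dz2 <- matrix((fwd$p - y) / B, ncol = 1L)
  g <- list()
  g$fc2_W <- crossprod(fwd$features, dz2)
  g$fc2_b <- sum(dz2)
  da1 <- dz2 %*% t(model$fc2$W)  # B x n_features
  dz1 <- da1 * (fwd$features > 0)
  g$fc1_W <- crossprod(fwd$h_last, dz1)
  g$fc1_b <- colSums(dz1)
  dh_last <- dz1 %*% t(model$fc1$W)
  zero <- matrix(0, B, model$l2$units)
  d_out2 <- c(rep(list(zero), Tn - 1L), list(dh_last))
  bk2 <- lstm_backward(model$l2, fwd$l2$cache, d_out2, masks$in2, masks$rec2)
  g$l2_W <- bk2$dW; g$l2_U <- bk2$dU; g$l2_b <- bk2$db
  bk1 <- lstm_backward(model$l1, fwd$l1$cache, bk2$d_x, masks$in1, masks$rec1)
  g$l1_W <- bk1$dW; g$l1_U <- bk1$dU; g$l1_b <- bk1$db
  g
}

model_param_refs <- function() {
  list(l1_W = c("l1", "W"), l1_U = c("l1", "U"), l1_b = c("l1", "b"),
       l2_W = c("l2", "W"), l2_U = c("l2", "U"), l2_b = c("l2", "b"),
       fc1_W = c("fc1", "W"), fc1_b = c("fc1", "b"),
       fc2_W = c("fc2", "W"), fc2_b = c("fc2", "b"))
}

get_param <- function(model, ref) model[[ref[1L]]][[ref[2L]]]
set_param <- function(model, ref, value) {
  model[[ref[1L]]][[ref[2L]]] <- value
  model
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

draw_masks <- function(model, B) {
  p_in <- model$dropout[1L]; p_rec <- model$dropout[2L]
  mk <- function(n, m, p) {
    if (p <= 0) return(NULL)
    matrix(stats::rbinom(n * m, 1L, 1 - p) / (1 - p), n, m)
  }
  list(in1 = mk(B, model$n_rows, p_in), rec1 = mk(B, model$l1$units, p_rec),
       in2 = mk(B, model$l1$units, p_in), rec2 = mk(B, model$l2$units, p_rec))
}

as_rsm_array <- function(x, n_rows, n_cycles) {
  if (is.array(x) && length(dim(x)) == 3L) {
    arr <- x
  } else {
    if (inherits(x, "dia_rsm")) x <- list(x)
    if (is.matrix(x)) x <- list(x)
    mats <- lapply(x, function(m) if (inherits(m, "dia_rsm")) m$matrix else m)
    arr <- array(0, dim = c(length(mats), nrow(mats[[1L]]), ncol(mats[[1L]])))
    for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  }
  if (dim(arr)[2L] != n_rows || dim(arr)[3L] != n_cycles) {
    stop("RSM shape ", dim(arr)[2L], " x ", dim(arr)[3L],
         " does not match the model input ", n_rows, " x ", n_cycles)
  }
  arr
}

#' Train the deep representation model
#'
#' Minimises binary cross-entropy between targets (label 1) and decoys
#' (label 0) with Adam. The training/validation split is 7:3 and honours a
#' per-precursor grouping: no RSM of one precursor appears in both splits.
#' Weights from the epoch with the best validation loss are kept; training
#' stops early when the validation loss has not improved for
#' \code{patience} epochs.
#'
#' @param model A \code{dia_rep_model}.
#' @param rsms List of normalized RSMs (or matrices), or a 3D array
#'   (samples x rows x cycles).
#' @param labels Binary labels (1 = target, 0 = decoy).
#' @param epochs,batch_size,lr Optimisation settings.
#' @param val_fraction Validation share of the data.
#' @param groups Optional per-sample precursor identifiers for the
#'   group-aware split.
#' @param patience Early-stopping patience in epochs.
#' @param seed Integer seed (shuffling, dropout masks, split).
#' @param verbose Print per-epoch losses.
#' @return The trained model, with a \code{history} data.frame.
#' @export
train_rep_model <- function(model, rsms, labels, epochs = 10L,
                            batch_size = 256L, lr = 1e-3,
                            val_fraction = 0.3, groups = NULL,
                            patience = 10L, seed = 1L, verbose = FALSE) {
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L) {
    stop("training requires both classes (targets and decoys)")
  }
  arr <- as_rsm_array(rsms, model$n_rows, model$n_cycles)
  n <- dim(arr)[1L]
  stopifnot(length(y) == n)
  if (is.null(groups)) groups <- seq_len(n)
  if (epochs <= 0L) return(model)

  with_local_seed(seed, {
    grp <- unique(groups)
    val_grp <- sample(grp, size = floor(length(grp) * val_fraction))
    val_idx <- which(groups %in% val_grp)
    tr_idx <- setdiff(seq_len(n), val_idx)

    refs <- model_param_refs()
    adam_m <- lapply(refs, function(r) get_param(model, r) * 0)
    adam_v <- adam_m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0L
    hist <- data.frame(epoch = integer(), loss = numeric(),
                       val_loss = numeric())
    best <- list(loss = Inf, model = model, epoch = 0L)
    wait <- 0L

    val_arr <- arr[val_idx, , , drop = FALSE]
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; n_seen <- 0L
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        xb <- arr[idx, , , drop = FALSE]
        yb <- y[idx]
        masks <- draw_masks(model, length(idx))
        fwd <- rep_forward(model, xb, masks, keep_cache = TRUE)
        ep_loss <- ep_loss + bce_loss(fwd$p, yb) * length(idx)
        n_seen <- n_seen + length(idx)
        grads <- rep_backward(model, fwd, yb, masks)
        step <- step + 1L
        for (nm in names(refs)) {
          gv <- grads[[nm]]
          pv <- get_param(model, refs[[nm]])
          if (is.null(dim(pv))) gv <- as.vector(gv)
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gv
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gv^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          model <- set_param(model, refs[[nm]],
                             pv - lr * mhat / (sqrt(vhat) + eps))
        }
      }
      val_p <- rep_forward(model, val_arr)$p
      val_loss <- bce_loss(val_p, y[val_idx])
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n_seen,
                                     val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %d  loss %.4f  val_loss %.4f", ep,
                        ep_loss / n_seen, val_loss))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, model = model, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    model <- best$model
    model$trained <- TRUE
    model$history <- hist
    model
  })
}

#' Predict deep features and discriminant scores
#'
#' Inference is deterministic (dropout disabled) and pure; batch prediction
#' equals per-item prediction.
#'
#' @param object A \code{dia_rep_model}.
#' @param newdata RSM(s): a \code{dia_rsm}, matrix, list thereof, or a 3D
#'   array. Inputs should be normalized (see \code{\link{normalize_rsm}}).
#' @param type "dds" (numeric vector), "features" (matrix) or "both".
#' @param batch_size Forward-pass batch size.
#' @param use_compiled Use the compiled forward pass (bit-identical to the
#'   R reference; set \code{FALSE} to force the reference path).
#' @param ... Unused.
#' @export
predict.dia_rep_model <- function(object, newdata, type = c("dds", "features", "both"),
                                  batch_size = 2048L, use_compiled = TRUE,
                                  ...) {
  type <- match.arg(type)
  arr <- as_rsm_array(newdata, object$n_rows, object$n_cycles)
  n <- dim(arr)[1L]
  dds <- numeric(n)
  feats <- matrix(0, n, object$n_features)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- arr[idx, , , drop = FALSE]
    fwd <- if (use_compiled) {
      out <- rep_forward_cpp(xb, object$l1$W, object$l1$U, object$l1$b,
                             object$l2$W, object$l2$U, object$l2$b,
                             object$fc1$W, object$fc1$b,
                             as.numeric(object$fc2$W), object$fc2$b)
      list(p = as.vector(out$p), features = out$features)
    } else {
      rep_forward(object, xb)
    }
    dds[idx] <- fwd$p
    feats[idx, ] <- fwd$features
  }
  switch(type, dds = dds, features = feats,
         both = list(dds = dds, features = feats))
}

#' Embed one RSM
#'
#' @param model A trained \code{dia_rep_model}.
#' @param rsm A (normalized) \code{dia_rsm} or matrix.
#' @return List with \code{features} (length-16 numeric) and \code{dds}.
#' @export
embed_rsm <- function(model, rsm) {
  out <- predict(model, rsm, type = "both")
  list(features = drop(out$features), dds = out$dds)
}
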