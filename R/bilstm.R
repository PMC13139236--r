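# Bidirectional LSTM binary classifier over fused graph descriptors.
# The recurrent cell, backpropagation through time and the Adam optimiser
# are implemented here; gradients are validated against finite differences
# in the test suite. Default hyperparameters: two stacked BiLSTM layers of
# 128 and 64 units, dropout 0.4, sigmoid head, Adam at learning rate 5e-4,
# binary cross-entropy, 250 epochs, batch size 64, one timestep per sample
# (the fused descriptor is not a time series).

.mf_sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM cell parameters
#'
#' Combines the four gate weight matrices acting on the concatenation
#' `[h_prev, x]` (input, forget, candidate, output — each of shape
#' `(hidden + input) x hidden`) and their bias vectors into one packed
#' parameter object. With `seed` given, weights are Glorot-uniform draws
#' and biases are zero except for the forget gate, initialised to 1 so
#' early training does not erase the cell state.
#'
#' @param input_size,hidden_size dimensions of the cell.
#' @param seed integer seed for random initialisation; omit to get zeros.
#' @return an `lstm_params` object with fields `W` (`(hidden + input) x
#'   4 hidden`, gate blocks ordered input/forget/candidate/output), `b`,
#'   `hidden_size`, `input_size`.
#' @export
lstm_params <- function(input_size, hidden_size, seed = NULL) {
  rows <- hidden_size + input_size
  if (is.null(seed)) {
    W <- matrix(0, rows, 4L * hidden_size)
  } else {
    W <- withr::with_seed(seed, .mf_glorot(rows, 4L * hidden_size))
  }
  b <- numeric(4L * hidden_size)
  b[hidden_size + seq_len(hidden_size)] <- if (is.null(seed)) 0 else 1
  structure(list(W = W, b = b, hidden_size = as.integer(hidden_size),
                 input_size = as.integer(input_size)),
            class = "lstm_params")
}

#' Build LSTM cell parameters from individual gate matrices
#'
#' @param w_i,w_f,w_c,w_o gate weight matrices (`(hidden + input) x
#'   hidden`), acting on `[h_prev, x]`.
#' @param b_i,b_f,b_c,b_o gate bias vectors (length `hidden`).
#' @return an `lstm_params` object.
#' @export
lstm_params_from_gates <- function(w_i, w_f, w_c, w_o,
                                   b_i = 0, b_f = 0, b_c = 0, b_o = 0) {
  h <- ncol(w_i)
  p <- lstm_params(nrow(w_i) - h, h)
  p$W <- cbind(w_i, w_f, w_c, w_o)
  p$b <- c(rep_len(b_i, h), rep_len(b_f, h), rep_len(b_c, h),
           rep_len(b_o, h))
  p
}

#' One LSTM cell step
#'
#' Applies the gate equations: input, forget and output gates through the
#' logistic sigmoid, candidate state through tanh, then
#' `c = f * c_prev + i * c_tilde` and `h = o * tanh(c)`. Every component of
#' the returned hidden state lies strictly inside (-1, 1).
#'
#' @param x input vector.
#' @param h_prev,c_prev previous hidden and cell state vectors.
#' @param params an `lstm_params` object.
#' @return list with updated `h` and `c`.
#' @export
lstm_cell_step <- function(x, h_prev, c_prev, params) {
  h <- params$hidden_size
  if (length(x) != params$input_size || length(h_prev) != h ||
      length(c_prev) != h)
    stop("shape mismatch in lstm_cell_step", call. = FALSE)
  z <- drop(c(h_prev, x) %*% params$W) + params$b
  i <- .mf_sigmoid(z[seq_len(h)])
  f <- .mf_sigmoid(z[h + seq_len(h)])
  g <- tanh(z[2L * h + seq_len(h)])
  o <- .mf_sigmoid(z[3L * h + seq_len(h)])
  cc <- f * c_prev + i * g
  list(h = o * tanh(cc), c = cc)
}

# Batched directional pass. xt: list of T matrices (B x input). Returns
# per-step outputs, the final hidden state and caches for backprop.
.mf_dir_forward <- function(xt, W, b, h, reverse = FALSE) {
  Tn <- length(xt); B <- nrow(xt[[1L]])
  steps <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  out <- vector("list", Tn); cache <- vector("list", Tn)
  for (t in steps) {
    Z <- cbind(H, xt[[t]]) %*% W
    Z <- Z + rep(b, each = nrow(Z))
    i <- .mf_sigmoid(Z[, seq_len(h), drop = FALSE])
    f <- .mf_sigmoid(Z[, h + seq_len(h), drop = FALSE])
    g <- tanh(Z[, 2L * h + seq_len(h), drop = FALSE])
    o <- .mf_sigmoid(Z[, 3L * h + seq_len(h), drop = FALSE])
    Cn <- f * C + i * g
    tc <- tanh(Cn)
    Hn <- o * tc
    cache[[t]] <- list(Hprev = H, Cprev = C, i = i, f = f, g = g, o = o,
                       tc = tc, x = xt[[t]])
    H <- Hn; C <- Cn
    out[[t]] <- Hn
  }
  list(out = out, last = H, cache = cache)
}

# Backprop through one direction. dout: list of per-step output gradients
# (NULL entries mean zero). Returns parameter gradients and per-step input
# gradients.
.mf_dir_backward <- function(dout, cache, W, h, reverse = FALSE) {
  Tn <- length(cache)
  steps <- if (reverse) seq_len(Tn) else rev(seq_len(Tn))
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dh <- 0; dc <- 0
  dx <- vector("list", Tn)
  for (t in steps) {
    cc <- cache[[t]]
    dh_t <- if (is.null(dout[[t]])) dh else dout[[t]] + dh
    dc <- dc + dh_t * cc$o * (1 - cc$tc^2)
    dZ <- cbind((dc * cc$g) * cc$i * (1 - cc$i),
                (dc * cc$Cprev) * cc$f * (1 - cc$f),
                (dc * cc$i) * (1 - cc$g^2),
                (dh_t * cc$tc) * cc$o * (1 - cc$o))
    dW <- dW + crossprod(cbind(cc$Hprev, cc$x), dZ)
    db <- db + colSums(dZ)
    dHX <- tcrossprod(dZ, W)
    dh <- dHX[, seq_len(h), drop = FALSE]
    dx[[t]] <- dHX[, -seq_len(h), drop = FALSE]
    dc <- dc * cc$f
  }
  list(dW = dW, db = db, dx = dx)
}

#' Bidirectional LSTM forward pass over one sequence
#'
#' Runs a forward LSTM over `t = 1..T` and a backward LSTM over `t = T..1`
#' from zero initial states and concatenates the per-step hidden states, so
#' the output at step `t` is `[h_fwd_t || h_bwd_t]` with width
#' `2 * hidden`.
#'
#' @param sequence `T x d` matrix (one sample).
#' @param fwd_params,bwd_params `lstm_params` for the two directions.
#' @return `T x (2 * hidden)` matrix.
#' @export
bilstm_forward <- function(sequence, fwd_params, bwd_params) {
  if (is.null(dim(sequence))) sequence <- matrix(sequence, nrow = 1L)
  if (ncol(sequence) != fwd_params$input_size)
    stop("shape mismatch in bilstm_forward", call. = FALSE)
  xt <- lapply(seq_len(nrow(sequence)), function(t)
    sequence[t, , drop = FALSE])
  f <- .mf_dir_forward(xt, fwd_params$W, fwd_params$b,
                       fwd_params$hidden_size, reverse = FALSE)
  b <- .mf_dir_forward(xt, bwd_params$W, bwd_params$b,
                       bwd_params$hidden_size, reverse = TRUE)
  do.call(rbind, lapply(seq_along(xt), function(t)
    cbind(f$out[[t]], b$out[[t]])))
}

#' Classifier configuration
#'
#' Hyperparameters of the stacked BiLSTM binary classifier. The defaults
#' are the working configuration of the method: BiLSTM units 128 then 64,
#' dropout 0.4 after each recurrent layer, sigmoid output, Adam with
#' learning rate 0.0005, binary cross-entropy loss, 250 epochs, batch size
#' 64 and a single timestep per sample. Early stopping watches validation
#' ROC-AUC with patience 20 and restores the best epoch's weights.
#'
#' @param units_layer1,units_layer2 hidden units per direction.
#' @param dropout dropout rate after each BiLSTM layer.
#' @param learning_rate Adam step size.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param timesteps sequence length the feature vector is reshaped to; the
#'   feature width must be divisible by it.
#' @param early_stopping_patience epochs without validation ROC-AUC
#'   improvement before stopping (ignored without a validation set).
#' @param standardize z-score features using training-set statistics.
#' @param seed integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(units_layer1 = 128L, units_layer2 = 64L,
                              dropout = 0.4, learning_rate = 5e-4,
                              epochs = 250L, batch_size = 64L,
                              timesteps = 1L, early_stopping_patience = 20L,
                              standardize = TRUE, seed = 1L) {
  structure(list(units_layer1 = as.integer(units_layer1),
                 units_layer2 = as.integer(units_layer2),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 timesteps = as.integer(timesteps),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 standardize = isTRUE(standardize),
                 optimizer = "adam", loss = "binary_crossentropy",
                 output = "sigmoid", seed = as.integer(seed)),
            class = "classifier_config")
}

.mf_init_classifier <- function(d_in, cfg) {
  h1 <- cfg$units_layer1; h2 <- cfg$units_layer2
  if (cfg$timesteps == 1L) {
    # with a single timestep the recurrent weights multiply a zero state
    # and can never influence the output or receive gradient; drop them and
    # fold each bias into the weight matrix as a last row met by a constant
    # ones column, so every stored parameter is live and updates are pure
    # matrix operations
    mk <- function(ins, h) {
      W <- rbind(.mf_glorot(ins, 4L * h), 0)
      W[ins + 1L, h + seq_len(h)] <- 1  # forget-gate bias 1
      W
    }
    return(list(l1f_W = mk(d_in, h1), l1b_W = mk(d_in, h1),
                l2f_W = mk(2L * h1, h2), l2b_W = mk(2L * h1, h2),
                dense_w = .mf_glorot(2L * h2, 1L), dense_b = 0))
  }
  mk <- function(ins, h) {
    W <- .mf_glorot(ins + h, 4L * h)
    b <- numeric(4L * h); b[h + seq_len(h)] <- 1  # forget-gate bias 1
    list(W = W, b = b)
  }
  l1f <- mk(d_in, h1); l1b <- mk(d_in, h1)
  l2f <- mk(2L * h1, h2); l2b <- mk(2L * h1, h2)
  list(l1f_W = l1f$W, l1f_b = l1f$b, l1b_W = l1b$W, l1b_b = l1b$b,
       l2f_W = l2f$W, l2f_b = l2f$b, l2b_W = l2b$W, l2b_b = l2b$b,
       dense_w = .mf_glorot(2L * h2, 1L), dense_b = 0)
}

# Single-timestep LSTM "step from zero state": gates act on the input
# alone. `x1` carries a trailing ones column that meets the bias row of W.
.mf_t1_cell <- function(x1, W, h) {
  Z <- x1 %*% W
  i <- .mf_sigmoid(Z[, seq_len(h), drop = FALSE])
  g <- tanh(Z[, 2L * h + seq_len(h), drop = FALSE])
  o <- .mf_sigmoid(Z[, 3L * h + seq_len(h), drop = FALSE])
  tc <- tanh(i * g)  # c = i * g (forget gate meets a zero cell state)
  list(h = o * tc, i = i, g = g, o = o, tc = tc, x1 = x1)
}

.mf_t1_cell_backward <- function(dh, cc, W, h) {
  dc <- dh * cc$o * (1 - cc$tc^2)
  dZ <- cbind((dc * cc$g) * cc$i * (1 - cc$i),
              matrix(0, nrow(dh), h),  # forget gate: no gradient at t = 1
              (dc * cc$i) * (1 - cc$g^2),
              (dh * cc$tc) * cc$o * (1 - cc$o))
  dx1 <- tcrossprod(dZ, W)
  list(dW = crossprod(cc$x1, dZ),
       dx = dx1[, -ncol(dx1), drop = FALSE])  # drop the ones column
}

# Dedicated single-timestep stack (the default configuration): both
# directions see the same single input, so the BiLSTM layer is two
# independent gated cells whose outputs are concatenated.
.mf_t1_stack_forward <- function(x, p, h1, h2, masks = NULL,
                                 keep_cache = FALSE) {
  x1 <- cbind(x, 1)
  f1 <- .mf_t1_cell(x1, p$l1f_W, h1)
  b1 <- .mf_t1_cell(x1, p$l1b_W, h1)
  out1 <- cbind(f1$h, b1$h)
  if (!is.null(masks)) out1 <- out1 * masks$m1[[1L]]
  out1c <- cbind(out1, 1)
  f2 <- .mf_t1_cell(out1c, p$l2f_W, h2)
  b2 <- .mf_t1_cell(out1c, p$l2b_W, h2)
  rep2 <- cbind(f2$h, b2$h)
  if (!is.null(masks)) rep2 <- rep2 * masks$m2
  z <- drop(rep2 %*% p$dense_w) + p$dense_b
  prob <- .mf_sigmoid(z)
  if (is.null(masks) && !keep_cache) return(list(prob = prob))
  list(prob = prob, rep2 = rep2, f1 = f1, b1 = b1, f2 = f2, b2 = b2)
}

.mf_t1_stack_backward <- function(fw, dz, p, h1, h2, masks = NULL) {
  g <- list()
  dzm <- matrix(dz, ncol = 1L)
  g$dense_w <- crossprod(fw$rep2, dzm)
  g$dense_b <- sum(dz)
  drep <- tcrossprod(dzm, p$dense_w)
  if (!is.null(masks)) drep <- drep * masks$m2
  bk2f <- .mf_t1_cell_backward(drep[, seq_len(h2), drop = FALSE], fw$f2,
                               p$l2f_W, h2)
  bk2b <- .mf_t1_cell_backward(drep[, h2 + seq_len(h2), drop = FALSE],
                               fw$b2, p$l2b_W, h2)
  g$l2f_W <- bk2f$dW
  g$l2b_W <- bk2b$dW
  d1 <- bk2f$dx + bk2b$dx
  if (!is.null(masks)) d1 <- d1 * masks$m1[[1L]]
  bk1f <- .mf_t1_cell_backward(d1[, seq_len(h1), drop = FALSE], fw$f1,
                               p$l1f_W, h1)
  bk1b <- .mf_t1_cell_backward(d1[, h1 + seq_len(h1), drop = FALSE],
                               fw$b1, p$l1b_W, h1)
  g$l1f_W <- bk1f$dW
  g$l1b_W <- bk1b$dW
  g
}

# Full stack forward. masks = NULL for inference. Returns probabilities and
# (when masks given or keep_cache) everything needed for backprop.
.mf_stack_forward <- function(xt, p, h1, h2, masks = NULL,
                              keep_cache = FALSE) {
  Tn <- length(xt)
  f1 <- .mf_dir_forward(xt, p$l1f_W, p$l1f_b, h1, FALSE)
  b1 <- .mf_dir_forward(xt, p$l1b_W, p$l1b_b, h1, TRUE)
  out1 <- lapply(seq_len(Tn), function(t) cbind(f1$out[[t]], b1$out[[t]]))
  if (!is.null(masks)) out1 <- Map(`*`, out1, masks$m1)
  f2 <- .mf_dir_forward(out1, p$l2f_W, p$l2f_b, h2, FALSE)
  b2 <- .mf_dir_forward(out1, p$l2b_W, p$l2b_b, h2, TRUE)
  rep2 <- cbind(f2$last, b2$last)
  if (!is.null(masks)) rep2 <- rep2 * masks$m2
  z <- drop(rep2 %*% p$dense_w) + p$dense_b
  prob <- .mf_sigmoid(z)
  if (is.null(masks) && !keep_cache) return(list(prob = prob))
  list(prob = prob, rep2 = rep2, f1 = f1, b1 = b1, f2 = f2, b2 = b2,
       out1 = out1)
}

.mf_stack_backward <- function(fw, dz, p, h1, h2, Tn, masks = NULL) {
  g <- list()
  dzm <- matrix(dz, ncol = 1L)
  g$dense_w <- crossprod(fw$rep2, dzm)
  g$dense_b <- sum(dz)
  drep <- dzm %*% t(p$dense_w)
  if (!is.null(masks)) drep <- drep * masks$m2
  dout_f2 <- vector("list", Tn); dout_b2 <- vector("list", Tn)
  dout_f2[[Tn]] <- drep[, seq_len(h2), drop = FALSE]
  dout_b2[[1L]] <- drep[, h2 + seq_len(h2), drop = FALSE]
  bk2f <- .mf_dir_backward(dout_f2, fw$f2$cache, p$l2f_W, h2, FALSE)
  bk2b <- .mf_dir_backward(dout_b2, fw$b2$cache, p$l2b_W, h2, TRUE)
  g$l2f_W <- bk2f$dW; g$l2f_b <- bk2f$db
  g$l2b_W <- bk2b$dW; g$l2b_b <- bk2b$db
  dout_f1 <- vector("list", Tn); dout_b1 <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    d1 <- bk2f$dx[[t]] + bk2b$dx[[t]]
    if (!is.null(masks)) d1 <- d1 * masks$m1[[t]]
    dout_f1[[t]] <- d1[, seq_len(h1), drop = FALSE]
    dout_b1[[t]] <- d1[, h1 + seq_len(h1), drop = FALSE]
  }
  bk1f <- .mf_dir_backward(dout_f1, fw$f1$cache, p$l1f_W, h1, FALSE)
  bk1b <- .mf_dir_backward(dout_b1, fw$b1$cache, p$l1b_W, h1, TRUE)
  g$l1f_W <- bk1f$dW; g$l1f_b <- bk1f$db
  g$l1b_W <- bk1b$dW; g$l1b_b <- bk1b$db
  g
}

.mf_slice_timesteps <- function(x, Tn) {
  d <- ncol(x)
  if (d %% Tn != 0L)
    stop("feature width ", d, " not divisible by timesteps ", Tn,
         call. = FALSE)
  step <- d %/% Tn
  lapply(seq_len(Tn), function(t)
    x[, (t - 1L) * step + seq_len(step), drop = FALSE])
}

.mf_adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                          eps = 1e-7) {
  lrt <- lr * sqrt(1 - beta2^t) / (1 - beta1^t)  # bias-corrected step size
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]] * g[[nm]]
    p[[nm]] <- p[[nm]] - lrt * st$m[[nm]] / (sqrt(st$v[[nm]]) + eps)
  }
  list(p = p, st = st)
}

.mf_predict_raw <- function(p, x, cfg, chunk = 8192L) {
  n <- nrow(x)
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    xs <- x[s:e, , drop = FALSE]
    out[s:e] <- if (cfg$timesteps == 1L) {
      .mf_t1_stack_forward(xs, p, cfg$units_layer1, cfg$units_layer2)$prob
    } else {
      .mf_stack_forward(.mf_slice_timesteps(xs, cfg$timesteps), p,
                        cfg$units_layer1, cfg$units_layer2)$prob
    }
  }
  out
}

#' Train the BiLSTM classifier
#'
#' Fits the stacked BiLSTM (128 then 64 units per direction by default)
#' with dropout 0.4 and a sigmoid head on fused feature vectors, using Adam
#' and binary cross-entropy. Each feature vector becomes a length-
#' `timesteps` sequence (1 by default). The full metric suite is recorded
#' on the training and validation sets at every epoch; with a validation
#' set, early stopping restores the weights of the best validation ROC-AUC
#' epoch.
#'
#' @param x numeric feature matrix (rows are samples).
#' @param y binary labels; both classes must be present.
#' @param config a [classifier_config()].
#' @param x_val,y_val optional validation set.
#' @param verbose print per-epoch progress.
#' @return a `bilstm_model` with the fitted parameters, the per-epoch
#'   `history` data frame, `best_epoch` and the feature scaler.
#' @export
train_bilstm <- function(x, y, config = classifier_config(),
                         x_val = NULL, y_val = NULL, verbose = FALSE) {
  x <- as.matrix(x); y <- as.integer(y)
  stopifnot(nrow(x) == length(y))
  if (length(unique(y)) < 2L)
    stop("labels contain a single class; AUC is undefined", call. = FALSE)
  cfg <- config
  center <- scalev <- NULL
  if (cfg$standardize) {
    center <- colMeans(x)
    scalev <- apply(x, 2L, stats::sd); scalev[scalev == 0] <- 1
    x <- sweep(sweep(x, 2L, center), 2L, scalev, `/`)
    if (!is.null(x_val))
      x_val <- sweep(sweep(as.matrix(x_val), 2L, center), 2L, scalev, `/`)
  } else if (!is.null(x_val)) x_val <- as.matrix(x_val)
  n <- nrow(x)
  h1 <- cfg$units_layer1; h2 <- cfg$units_layer2; Tn <- cfg$timesteps
  d_step <- ncol(x) %/% Tn
  has_val <- !is.null(x_val) && !is.null(y_val)

  hist_rows <- vector("list", cfg$epochs)
  best <- list(auc = -Inf, epoch = 0L, p = NULL)
  wait <- 0L

  p <- NULL
  withr::with_seed(cfg$seed, {
    p <- .mf_init_classifier(d_step, cfg)
    st <- list(m = lapply(p, function(z) z * 0),
               v = lapply(p, function(z) z * 0))
    adam_t <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      idx <- sample(n)
      for (s in seq(1L, n, by = cfg$batch_size)) {
        take <- idx[s:min(s + cfg$batch_size - 1L, n)]
        B <- length(take)
        xb <- x[take, , drop = FALSE]
        masks <- if (cfg$dropout > 0) {
          keep <- 1 - cfg$dropout
          list(m1 = lapply(seq_len(Tn), function(t)
            matrix(stats::rbinom(B * 2L * h1, 1L, keep) / keep, B, 2L * h1)),
            m2 = matrix(stats::rbinom(B * 2L * h2, 1L, keep) / keep,
                        B, 2L * h2))
        } else NULL
        if (Tn == 1L) {
          fw <- .mf_t1_stack_forward(xb, p, h1, h2, masks,
                                     keep_cache = TRUE)
          dz <- (fw$prob - y[take]) / B
          g <- .mf_t1_stack_backward(fw, dz, p, h1, h2, masks)
        } else {
          fw <- .mf_stack_forward(.mf_slice_timesteps(xb, Tn), p, h1, h2,
                                  masks, keep_cache = TRUE)
          dz <- (fw$prob - y[take]) / B
          g <- .mf_stack_backward(fw, dz, p, h1, h2, Tn, masks)
        }
        adam_t <- adam_t + 1L
        upd <- .mf_adam_step(p, g, st, cfg$learning_rate, adam_t)
        p <- upd$p; st <- upd$st
      }
      tr_scores <- .mf_predict_raw(p, x, cfg)
      tr <- evaluate_scores(tr_scores, y)
      row <- data.frame(epoch = epoch, train_loss = tr$loss,
                        train_roc_auc = tr$roc_auc,
                        train_prc_auc = tr$prc_auc, train_recall = tr$recall,
                        train_zero_one = tr$zero_one_loss,
                        val_loss = NA_real_, val_roc_auc = NA_real_,
                        val_prc_auc = NA_real_, val_recall = NA_real_,
                        val_zero_one = NA_real_)
      if (has_val) {
        va <- evaluate_scores(.mf_predict_raw(p, x_val, cfg),
                              as.integer(y_val))
        row$val_loss <- va$loss; row$val_roc_auc <- va$roc_auc
        row$val_prc_auc <- va$prc_auc; row$val_recall <- va$recall
        row$val_zero_one <- va$zero_one_loss
      }
      hist_rows[[epoch]] <- row
      if (verbose)
        message(sprintf("epoch %d loss %.4f auc %.4f%s", epoch, tr$loss,
                        tr$roc_auc,
                        if (has_val) sprintf(" val_auc %.4f",
                                             row$val_roc_auc) else ""))
      monitor <- if (has_val) row$val_roc_auc else tr$roc_auc
      if (monitor > best$auc) {
        best <- list(auc = monitor, epoch = epoch, p = p)
        wait <- 0L
      } else if (has_val) {
        wait <- wait + 1L
        if (wait >= cfg$early_stopping_patience) break
      }
    }
  })

  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)])
  structure(list(params = if (!is.null(best$p)) best$p else p,
                 config = cfg, history = history,
                 best_epoch = best$epoch, center = center, scale = scalev,
                 d_in = ncol(x)),
            class = "bilstm_model")
}

#' Predict class probabilities
#'
#' Forward pass with dropout disabled; repeated calls on the same input
#' give identical outputs.
#'
#' @param object a fitted `bilstm_model`.
#' @param newdata numeric feature matrix with the training feature width.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.bilstm_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$d_in)
    stop("feature width ", ncol(x), " does not match training width ",
         object$d_in, call. = FALSE)
  if (!is.null(object$center))
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, `/`)
  .mf_predict_raw(object$params, x, object$config)
}
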