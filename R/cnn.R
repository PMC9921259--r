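# Five-block 1-D convolutional network used as a trainable feature
# extractor: each block is convolution (same-length, no bias) -> batch
# normalization -> ReLU -> average pooling; the flattened block-5 output
# passes a dropout layer and a two-unit fully connected head predicting
# (SBP, DBP) in mmHg. Training minimizes the half-mean-squared-error loss
# with mini-batch stochastic gradient descent.
#
# Convolutions are evaluated as im2col gathers followed by BLAS matrix
# products; batches are stored as (channels, time, sample) arrays.

#' CNN architecture configuration
#'
#' @param channels Output channels of the five blocks.
#' @param kernel_len Odd convolution kernel length in samples.
#' @param pool_len Average-pooling width (and stride).
#' @param dropout_rate Dropout fraction before the fully connected head.
#' @param input_channels Input channels (2: ECG and PPG rows).
#' @param input_len Input length in samples (125 = one beat at 125 Hz).
#' @param fc_units Output units (2: SBP and DBP).
#' @return An object of class `bp_cnn_config`.
#' @export
cnn_config <- function(channels = c(16, 32, 64, 128, 256), kernel_len = 5,
                       pool_len = 2, dropout_rate = 0.20,
                       input_channels = 2, input_len = 125, fc_units = 2) {
  if (length(channels) != 5) stop_cuffbp("the network has five blocks; `channels` must have length 5")
  if (kernel_len %% 2 != 1) stop_cuffbp("kernel_len must be odd (same-length convolution)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_cuffbp("dropout_rate must be in [0, 1)")
  if (fc_units != 2) stop_cuffbp("the head has two units (SBP, DBP)")
  structure(list(channels = as.integer(channels), kernel_len = as.integer(kernel_len),
                 pool_len = as.integer(pool_len), dropout_rate = dropout_rate,
                 input_channels = as.integer(input_channels),
                 input_len = as.integer(input_len), fc_units = as.integer(fc_units)),
            class = "bp_cnn_config")
}

#' Training configuration for the CNN
#'
#' The learning rate at epoch e is
#' `initial_lr * lr_drop^floor((e - 1) / lr_step)`. With the default
#' `lr_step = 10` the rate is multiplied by 0.1 once per ten epochs;
#' `lr_step = 1` gives the per-epoch drop reading (which freezes learning
#' within a handful of epochs).
#'
#' @param initial_lr Initial learning rate.
#' @param lr_drop Multiplicative drop factor in (0, 1].
#' @param lr_step Epochs between drops.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param momentum SGD momentum (0 gives plain SGD).
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @return An object of class `bp_train_config`.
#' @export
train_config <- function(initial_lr = 0.001, lr_drop = 0.1, lr_step = 10,
                         epochs = 30, batch_size = 60, momentum = 0.9,
                         seed = 1L) {
  check_number(initial_lr, "initial_lr", 1e-12, Inf)
  check_number(lr_drop, "lr_drop", 1e-12, 1)
  check_number(lr_step, "lr_step", 1, Inf)
  check_number(epochs, "epochs", 1, Inf)
  check_number(batch_size, "batch_size", 1, Inf)
  check_number(momentum, "momentum", 0, 1 - 1e-9)
  structure(list(initial_lr = initial_lr, lr_drop = lr_drop,
                 lr_step = as.integer(lr_step), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed)),
            class = "bp_train_config")
}

#' Per-epoch learning rate of the piecewise-drop schedule
#'
#' @param config A [train_config()].
#' @param epoch Epoch number (1-based).
#' @return The learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr * config$lr_drop^((epoch - 1) %/% config$lr_step)
}

#' Build an untrained CNN
#'
#' Convolution weights use He initialization; batch-norm scales start at 1,
#' shifts at 0. The temporal length shrinks by floor division at each
#' pooling (125 -> 62 -> 31 -> 15 -> 7 -> 3 with the defaults), so the
#' flattened feature dimension is `channels[5] * 3 = 768`.
#'
#' @param config A [cnn_config()].
#' @param seed Seed for weight initialization.
#' @return An object of class `bp_cnn` with `feature_dim`, per-layer shapes
#'   and parameters; `trained` is `FALSE` until [cnn_train()] runs.
#' @export
cnn_build <- function(config = cnn_config(), seed = 1L) {
  k <- config$kernel_len
  c_in <- c(config$input_channels, config$channels[-5])
  lens <- integer(6)
  lens[1] <- config$input_len
  for (i in 1:5) lens[i + 1] <- lens[i] %/% config$pool_len
  params <- with_seed(derive_seed(seed, "cnn-init"), {
    conv <- lapply(1:5, function(i) {
      fan_in <- c_in[i] * k
      matrix(rnorm(config$channels[i] * fan_in, 0, sqrt(2 / fan_in)),
             nrow = config$channels[i])
    })
    fdim <- config$channels[5] * lens[6]
    list(
      conv = conv,
      bn = lapply(1:5, function(i) list(
        gamma = rep(1, config$channels[i]), beta = rep(0, config$channels[i]),
        run_mean = rep(0, config$channels[i]), run_var = rep(1, config$channels[i])
      )),
      fc_W = matrix(rnorm(config$fc_units * fdim, 0, sqrt(1 / fdim)),
                    nrow = config$fc_units),
      fc_b = rep(0, config$fc_units)
    )
  })
  structure(list(config = config, params = params,
                 lens = lens, c_in = c_in,
                 feature_dim = config$channels[5] * lens[6],
                 loss_history = numeric(0), trained = FALSE,
                 seed = as.integer(seed),
                 .idx_cache = new.env(parent = emptyenv())),
            class = "bp_cnn")
}

#' @export
print.bp_cnn <- function(x, ...) {
  cat(sprintf("<bp_cnn: 5 blocks [%s], kernel %d, feature_dim %d, %s>\n",
              paste(x$config$channels, collapse = ","), x$config$kernel_len,
              x$feature_dim,
              if (x$trained) sprintf("trained (%d epochs)", length(x$loss_history))
              else "untrained"))
  invisible(x)
}

# --- layer primitives ------------------------------------------------------

# Cached im2col gather indices for a (C, L, N) input, kernel k, zero pad.
im2col_idx <- function(model, C, L, N, k, pad) {
  key <- paste(C, L, N, sep = "x")
  cached <- model$.idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  Lp <- L + 2L * pad
  rowbase <- as.vector(outer(seq_len(C), (0:(k - 1)) * C, `+`))
  colbase <- as.vector(outer((0:(L - 1)) * C, (0:(N - 1)) * C * Lp, `+`))
  idx <- matrix(rep(rowbase, times = length(colbase)), nrow = length(rowbase)) +
    matrix(rep(colbase, each = length(rowbase)), nrow = length(rowbase))
  model$.idx_cache[[key]] <- idx
  idx
}

pad_time <- function(X, pad) {
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  Xp[, (pad + 1):(pad + d[2]), ] <- X
  Xp
}

conv_forward <- function(model, X, W, k) {
  d <- dim(X)
  pad <- (k - 1L) %/% 2L
  Xp <- pad_time(X, pad)
  idx <- im2col_idx(model, d[1], d[2], d[3], k, pad)
  cols <- Xp[as.vector(idx)]
  dim(cols) <- dim(idx)
  Ym <- W %*% cols
  Y <- Ym
  dim(Y) <- c(nrow(W), d[2], d[3])
  list(Y = Y, cols = cols, in_dim = d, pad = pad)
}

conv_backward <- function(dY, cache, W, k) {
  d <- cache$in_dim
  pad <- cache$pad
  dYm <- dY
  dim(dYm) <- c(dim(dY)[1], d[2] * d[3])
  dW <- tcrossprod(dYm, cache$cols)
  dcols <- crossprod(W, dYm) # (C_in*k) x (L*N)
  dXp <- array(0, c(d[1], d[2] + 2L * pad, d[3]))
  C <- d[1]
  for (j in seq_len(k)) {
    blk <- dcols[((j - 1L) * C + 1L):(j * C), , drop = FALSE]
    dim(blk) <- c(C, d[2], d[3])
    dXp[, j:(j + d[2] - 1L), ] <- dXp[, j:(j + d[2] - 1L), ] + blk
  }
  list(dW = dW, dX = dXp[, (pad + 1):(pad + d[2]), , drop = FALSE])
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(X, bn, training) {
  d <- dim(X)
  M <- X
  dim(M) <- c(d[1], d[2] * d[3])
  if (training) {
    mu <- rowMeans(M)
    v <- rowMeans(M * M) - mu^2
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (M - mu) * invstd
  Y <- bn$gamma * xhat + bn$beta
  dim(Y) <- d
  out <- list(Y = Y, xhat = xhat, invstd = invstd, dims = d)
  if (training) {
    out$new_mean <- (1 - BN_MOMENTUM) * bn$run_mean + BN_MOMENTUM * mu
    out$new_var <- (1 - BN_MOMENTUM) * bn$run_var + BN_MOMENTUM * v
  }
  out
}

bn_backward <- function(dY, cache, bn) {
  d <- cache$dims
  dYm <- dY
  dim(dYm) <- c(d[1], d[2] * d[3])
  m <- d[2] * d[3]
  dgamma <- rowSums(dYm * cache$xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * bn$gamma
  dX <- (cache$invstd / m) *
    (m * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  dim(dX) <- d
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

pool_forward <- function(X, p) {
  d <- dim(X)
  L2 <- (d[2] %/% p) * p
  Xc <- X[, seq_len(L2), , drop = FALSE]
  dim(Xc) <- c(d[1], p, L2 %/% p, d[3])
  Y <- Xc[, 1, , , drop = FALSE]
  for (j in 2:p) Y <- Y + Xc[, j, , , drop = FALSE]
  Y <- Y / p
  dim(Y) <- c(d[1], L2 %/% p, d[3])
  list(Y = Y, in_dim = d, p = p)
}

pool_backward <- function(dY, cache) {
  d <- cache$in_dim
  p <- cache$p
  Lo <- dim(dY)[2]
  dX <- array(0, d)
  rep_d <- array(0, c(d[1], p, Lo, d[3]))
  for (j in seq_len(p)) rep_d[, j, , ] <- dY / p
  dim(rep_d) <- c(d[1], p * Lo, d[3])
  dX[, seq_len(p * Lo), ] <- rep_d
  dX
}

# Full forward pass. Returns predictions, flattened block-5 features and
# (when training) the caches needed for backprop.
cnn_forward_internal <- function(model, X, training = FALSE, drop_mask = NULL) {
  cfg <- model$config
  caches <- if (training) vector("list", 5) else NULL
  A <- X
  for (i in 1:5) {
    cv <- conv_forward(model, A, model$params$conv[[i]], cfg$kernel_len)
    bn <- bn_forward(cv$Y, model$params$bn[[i]], training)
    relu_mask <- bn$Y > 0
    Z <- bn$Y * relu_mask
    pl <- pool_forward(Z, cfg$pool_len)
    if (training) caches[[i]] <- list(conv = cv, bn = bn, relu = relu_mask, pool = pl)
    A <- pl$Y
  }
  N <- dim(A)[3]
  F <- A
  dim(F) <- c(model$feature_dim, N)
  Fd <- if (training && !is.null(drop_mask)) F * drop_mask else F
  pred <- model$params$fc_W %*% Fd + model$params$fc_b
  list(pred = pred, features = F, dropped = Fd, caches = caches)
}

#' Half-mean-squared-error loss
#'
#' `sum((pred - target)^2) / (2 * R)` where `R` is the total number of
#' predicted values (both targets, all beats).
#'
#' @param pred,target Equal-dimension numeric matrices/vectors.
#' @return The loss value.
#' @export
half_mse <- function(pred, target) {
  sum((pred - target)^2) / (2 * length(target))
}

#' Train the CNN with mini-batch SGD
#'
#' Runs `epochs * floor(N / batch_size)` parameter updates under the
#' piecewise-drop learning-rate schedule, recording the mean half-MSE of
#' each epoch. The output bias is initialized at the training-target means
#' so the head starts from the cohort average rather than zero mmHg.
#' Deterministic for a fixed seed on one platform (single-threaded BLAS).
#'
#' @param model A [cnn_build()] result.
#' @param x Input array of shape (2, input_len, N) — see [beats_to_array()].
#' @param y Target matrix of shape (2, N): SBP and DBP rows, mmHg.
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss.
#' @return The trained model with `loss_history` filled.
#' @export
cnn_train <- function(model, x, y, config = train_config(), verbose = FALSE) {
  stopifnot(length(dim(x)) == 3, nrow(y) == model$config$fc_units)
  N <- dim(x)[3]
  if (N < 2 * config$batch_size) {
    stop_cuffbp(sprintf("need at least 2 * batch_size = %d beats, got %d",
                        2 * config$batch_size, N))
  }
  if (any(!is.finite(y))) stop_cuffbp("targets contain non-finite values")
  p <- model$params
  p$fc_b <- rowMeans(y)
  vel <- list(conv = lapply(p$conv, function(w) w * 0),
              bn_g = lapply(p$bn, function(b) b$gamma * 0),
              bn_b = lapply(p$bn, function(b) b$beta * 0),
              fc_W = p$fc_W * 0, fc_b = p$fc_b * 0)
  model$params <- p
  n_batch <- N %/% config$batch_size
  loss_hist <- numeric(config$epochs)
  drop_p <- model$config$dropout_rate
  fdim <- model$feature_dim
  for (e in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, e)
    perm <- with_seed(derive_seed(config$seed, "shuffle", e), sample.int(N))
    masks_seed <- derive_seed(config$seed, "dropout", e)
    batch_losses <- numeric(n_batch)
    for (b in seq_len(n_batch)) {
      sel <- perm[((b - 1) * config$batch_size + 1):(b * config$batch_size)]
      Xb <- x[, , sel, drop = FALSE]
      Yb <- y[, sel, drop = FALSE]
      drop_mask <- if (drop_p > 0) {
        with_seed((masks_seed + b) %% 2147483647, {
          matrix(rbinom(fdim * length(sel), 1, 1 - drop_p) / (1 - drop_p),
                 nrow = fdim)
        })
      } else {
        NULL
      }
      fw <- cnn_forward_internal(model, Xb, training = TRUE, drop_mask = drop_mask)
      loss <- half_mse(fw$pred, Yb)
      if (!is.finite(loss)) {
        stop_cuffbp(sprintf("non-finite training loss at epoch %d, batch %d", e, b))
      }
      batch_losses[b] <- loss
      grads <- cnn_backward_internal(model, fw, Yb, drop_mask)
      model <- sgd_step(model, grads, vel, lr, config$momentum)
      vel <- model$.vel
      # commit batch-norm running stats
      for (i in 1:5) {
        model$params$bn[[i]]$run_mean <- fw$caches[[i]]$bn$new_mean
        model$params$bn[[i]]$run_var <- fw$caches[[i]]$bn$new_var
      }
    }
    loss_hist[e] <- mean(batch_losses)
    if (verbose) {
      log_line("epoch %d/%d lr %.2g half-MSE %.3f", e, config$epochs, lr, loss_hist[e])
    }
  }
  model$.vel <- NULL
  model$loss_history <- loss_hist
  model$trained <- TRUE
  model$train_config <- config
  model
}

cnn_backward_internal <- function(model, fw, Yb, drop_mask) {
  cfg <- model$config
  R <- length(Yb)
  dpred <- (fw$pred - Yb) / R
  dfc_W <- tcrossprod(dpred, fw$dropped)
  dfc_b <- rowSums(dpred)
  dFd <- crossprod(model$params$fc_W, dpred)
  dF <- if (!is.null(drop_mask)) dFd * drop_mask else dFd
  cache5 <- fw$caches[[5]]
  dA <- dF
  dim(dA) <- dim(cache5$pool$Y)
  grads <- list(conv = vector("list", 5), bn_g = vector("list", 5),
                bn_b = vector("list", 5), fc_W = dfc_W, fc_b = dfc_b)
  for (i in 5:1) {
    ch <- fw$caches[[i]]
    dZ <- pool_backward(dA, ch$pool)
    dBn <- dZ * ch$relu
    bnb <- bn_backward(dBn, ch$bn, model$params$bn[[i]])
    cvb <- conv_backward(bnb$dX, ch$conv, model$params$conv[[i]], cfg$kernel_len)
    grads$conv[[i]] <- cvb$dW
    grads$bn_g[[i]] <- bnb$dgamma
    grads$bn_b[[i]] <- bnb$dbeta
    dA <- cvb$dX
  }
  grads
}

sgd_step <- function(model, grads, vel, lr, momentum) {
  for (i in 1:5) {
    vel$conv[[i]] <- momentum * vel$conv[[i]] - lr * grads$conv[[i]]
    model$params$conv[[i]] <- model$params$conv[[i]] + vel$conv[[i]]
    vel$bn_g[[i]] <- momentum * vel$bn_g[[i]] - lr * grads$bn_g[[i]]
    model$params$bn[[i]]$gamma <- model$params$bn[[i]]$gamma + vel$bn_g[[i]]
    vel$bn_b[[i]] <- momentum * vel$bn_b[[i]] - lr * grads$bn_b[[i]]
    model$params$bn[[i]]$beta <- model$params$bn[[i]]$beta + vel$bn_b[[i]]
  }
  vel$fc_W <- momentum * vel$fc_W - lr * grads$fc_W
  model$params$fc_W <- model$params$fc_W + vel$fc_W
  vel$fc_b <- momentum * vel$fc_b - lr * grads$fc_b
  model$params$fc_b <- model$params$fc_b + vel$fc_b
  model$.vel <- vel
  model
}

#' Forward pass at inference (dropout off, frozen batch-norm statistics)
#'
#' @param model A `bp_cnn`.
#' @param x Input array (2, input_len, N).
#' @param batch Samples per forward chunk.
#' @return N x 2 matrix of (SBP, DBP) predictions in mmHg.
#' @export
cnn_predict <- function(model, x, batch = 512L) {
  out <- cnn_apply(model, x, batch)
  t(out$pred)
}

#' Extract learned features (flattened block-5 activations)
#'
#' Dropout is inactive and batch-norm uses its frozen running statistics, so
#' the features are deterministic and independent of batch composition. Rows
#' follow the input beat order.
#'
#' @param model A `bp_cnn`; a warning is issued if it is untrained (features
#'   then come from the random initialization).
#' @param x Input array (2, input_len, N).
#' @param batch Samples per forward chunk.
#' @return N x feature_dim matrix.
#' @export
cnn_features <- function(model, x, batch = 512L) {
  if (!isTRUE(model$trained)) {
    warning("extracting features from an untrained network", call. = FALSE)
  }
  out <- cnn_apply(model, x, batch)
  t(out$features)
}

cnn_apply <- function(model, x, batch) {
  stopifnot(length(dim(x)) == 3)
  N <- dim(x)[3]
  pred <- matrix(0, model$config$fc_units, N)
  feats <- matrix(0, model$feature_dim, N)
  starts <- seq.int(1L, N, by = batch)
  for (s in starts) {
    e <- min(s + batch - 1L, N)
    fw <- cnn_forward_internal(model, x[, , s:e, drop = FALSE], training = FALSE)
    pred[, s:e] <- fw$pred
    feats[, s:e] <- fw$features
  }
  list(pred = pred, features = feats)
}

#' Convert labelled beats to CNN inputs
#'
#' Stacks the ECG and PPG rows of each beat into a (2, beat_len, N) array
#' (the vertical ECG/PPG concatenation the network expects) and the labels
#' into a (2, N) target matrix.
#'
#' @param beats A `bp_beats` object.
#' @return A list with `x` (input array) and `y` (target matrix; rows SBP,
#'   DBP).
#' @export
beats_to_array <- function(beats) {
  nb <- nrow(beats$ecg_beats)
  wlen <- ncol(beats$ecg_beats)
  x <- array(0, c(2, wlen, nb))
  x[1, , ] <- t(beats$ecg_beats)
  x[2, , ] <- t(beats$ppg_beats)
  list(x = x, y = rbind(sbp = beats$sbp, dbp = beats$dbp))
}
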