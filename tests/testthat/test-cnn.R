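# CNN feature extractor: shapes, loss, learning-rate schedule, analytic
# gradients against finite differences, and inference determinism.

make_batch <- function(n, seed = 1, len = 125) {
  set.seed(seed)
  x <- array(rnorm(2 * len * n), c(2, len, n))
  y <- rbind(runif(n, 90, 160), runif(n, 50, 90))
  list(x = x, y = y)
}

test_that("forward pass honors the shape contract and pooling arithmetic", {
  m <- cnn_build(cnn_config(), seed = 1)
  # 125 -> 62 -> 31 -> 15 -> 7 -> 3, so features are 256 x 3 = 768
  expect_equal(m$lens, c(125L, 62L, 31L, 15L, 7L, 3L))
  expect_equal(m$feature_dim, 768)
  d <- make_batch(60)
  pred <- cnn_predict(m, d$x)
  expect_equal(dim(pred), c(60L, 2L))
  # dropout off at inference: repeated passes are identical
  expect_identical(pred, cnn_predict(m, d$x))
})

test_that("configuration invariants are enforced", {
  expect_error(cnn_config(channels = c(8, 16)), "five blocks")
  expect_error(cnn_config(dropout_rate = 1), "dropout_rate")
  expect_error(cnn_config(fc_units = 3), "two units")
  expect_error(cnn_config(kernel_len = 4), "odd")
})

test_that("the learning-rate schedule follows the piecewise drop", {
  tc <- train_config(initial_lr = 0.001, lr_drop = 0.1, lr_step = 10)
  expect_equal(sapply(1:30, function(e) lr_at_epoch(tc, e)),
               0.001 * 0.1^((0:29) %/% 10))
  literal <- train_config(lr_step = 1)
  expect_equal(lr_at_epoch(literal, 6), 0.001 * 0.1^5)
})

test_that("the loss equals the brute-force half-mean of squared residuals", {
  m <- cnn_build(cnn_config(), seed = 2)
  d <- make_batch(30, seed = 3)
  pred <- t(cnn_predict(m, d$x))
  expect_equal(half_mse(pred, d$y),
               sum((pred - d$y)^2) / (2 * length(d$y)))
})

test_that("backpropagated gradients match central finite differences", {
  m <- cnn_build(tiny_cnn_config(), seed = 4)
  d <- make_batch(4, seed = 5)
  loss_at <- function(model) {
    fw <- cuffbp:::cnn_forward_internal(model, d$x, training = TRUE)
    half_mse(fw$pred, d$y)
  }
  fw <- cuffbp:::cnn_forward_internal(m, d$x, training = TRUE)
  grads <- cuffbp:::cnn_backward_internal(m, fw, d$y, NULL)
  eps <- 1e-5
  fd_check <- function(get, set, g, picks) {
    for (i in picks) {
      mp <- set(m, get(m)[i] + eps, i)
      mm <- set(m, get(m)[i] - eps, i)
      fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
      expect_equal(g[i], fd, tolerance = 1e-4)
    }
  }
  for (blk in c(1L, 3L, 5L)) {
    fd_check(function(mo) mo$params$conv[[blk]],
             function(mo, v, i) { mo$params$conv[[blk]][i] <- v; mo },
             grads$conv[[blk]], c(1L, 5L))
    fd_check(function(mo) mo$params$bn[[blk]]$gamma,
             function(mo, v, i) { mo$params$bn[[blk]]$gamma[i] <- v; mo },
             grads$bn_g[[blk]], 1L)
    fd_check(function(mo) mo$params$bn[[blk]]$beta,
             function(mo, v, i) { mo$params$bn[[blk]]$beta[i] <- v; mo },
             grads$bn_b[[blk]], 2L)
  }
  fd_check(function(mo) mo$params$fc_W,
           function(mo, v, i) { mo$params$fc_W[i] <- v; mo },
           grads$fc_W, c(1L, 7L))
  fd_check(function(mo) mo$params$fc_b,
           function(mo, v, i) { mo$params$fc_b[i] <- v; mo },
           grads$fc_b, 1:2)
})

test_that("SGD training reduces the half-MSE and records every epoch", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 130)
  pre <- preprocess_record(rec)
  beats <- segment_record(pre)
  arr <- beats_to_array(beats)
  m <- cnn_build(cnn_config(), seed = 6)
  tc <- train_config(epochs = 3, batch_size = 60, seed = 6)
  mt <- cnn_train(m, arr$x, arr$y, tc)
  expect_length(mt$loss_history, 3)
  expect_lt(mt$loss_history[3], mt$loss_history[1])
  expect_true(mt$trained)
  # determinism under the same seed
  mt2 <- cnn_train(m, arr$x, arr$y, tc)
  expect_identical(mt$loss_history, mt2$loss_history)
  expect_identical(mt$params$fc_W, mt2$params$fc_W)
  expect_error(cnn_train(m, arr$x[, , 1:50, drop = FALSE], arr$y[, 1:50], tc),
               "batch_size")
})

test_that("features are deterministic, batch-independent and beat-ordered", {
  m <- cnn_build(tiny_cnn_config(), seed = 7)
  d <- make_batch(10, seed = 8)
  expect_warning(f <- cnn_features(m, d$x), "untrained")
  expect_equal(dim(f), c(10L, m$feature_dim))
  # identical beats give identical rows
  twin <- d$x[, , c(1, 1)]
  ftwin <- suppressWarnings(cnn_features(m, twin))
  expect_equal(ftwin[1, ], ftwin[2, ])
  # frozen batch-norm: a beat's features do not depend on its batch peers
  alone <- suppressWarnings(cnn_features(m, d$x[, , 1, drop = FALSE]))
  expect_equal(alone[1, ], f[1, ], tolerance = 1e-12)
})
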