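# Epsilon-SVR: kernel values, dual solver against a dense QP oracle and an
# independent SMO implementation, KKT properties, and grid-search CV.

test_that("RBF kernel values match the closed form", {
  x <- c(1, 2, 3)
  expect_equal(rbf_kernel(x, x, gamma = 10), 1)
  expect_equal(rbf_kernel(0, sqrt(0.1), gamma = 10), exp(-1))
  # monotone decay in gamma for distinct points
  v <- sapply(c(1, 10, 100), function(g) rbf_kernel(c(0, 0), c(0.3, 0.1), g))
  expect_true(all(diff(v) < 0))
  expect_error(rbf_kernel(1:3, 1:4, 1), "lengths")
  expect_error(rbf_kernel(1, 2, gamma = 0), "gamma")
})

test_that("flat targets give zero dual coefficients and a constant bias", {
  toy <- svr_toy(20)
  fit <- fit_svr(toy$x, rep(117.5, 20),
                 svr_config(cv_folds = 2, gamma_scale = "none"), seed = 1)
  expect_length(fit$dual_coef, 0)
  expect_equal(fit$bias, 117.5)
  expect_equal(predict(fit, toy$x), rep(117.5, 20))
})

test_that("the SMO solution matches a dense QP oracle on toy problems", {
  toy <- svr_toy(30, seed = 2)
  Z <- scale(toy$x)
  K <- exp(-10 * as.matrix(dist(Z))^2)
  for (prm in list(c(C = 10, eps = 0.01), c(C = 10, eps = 0.5),
                   c(C = 100, eps = 0.1))) {
    fit <- cuffbp:::svr_smo_cpp(K, toy$y, C = prm["C"], eps = prm["eps"],
                                tol = 1e-7)
    oracle <- svr_qp_oracle(K, toy$y, C = prm["C"], eps = prm["eps"])
    obj_fit <- svr_dual_objective(fit$beta, K, toy$y, prm["eps"])
    obj_orc <- svr_dual_objective(oracle$beta, K, toy$y, prm["eps"])
    expect_lt(abs(obj_fit - obj_orc) / abs(obj_orc), 1e-4)
    pred_fit <- as.numeric(K %*% fit$beta) + fit$b
    pred_orc <- as.numeric(K %*% oracle$beta) + oracle$b
    expect_lt(max(abs(pred_fit - pred_orc)), 1e-3)
  }
})

test_that("the solver agrees with an independent SMO implementation", {
  toy <- svr_toy(45, seed = 3)
  K <- exp(-2 * as.matrix(dist(toy$x))^2)
  fit <- cuffbp:::svr_smo_cpp(K, toy$y, C = 50, eps = 0.1, tol = 1e-7)
  ref <- e1071::svm(toy$x, toy$y, type = "eps-regression", kernel = "radial",
                    gamma = 2, cost = 50, epsilon = 0.1, scale = FALSE,
                    tolerance = 1e-7)
  expect_lt(max(abs((as.numeric(K %*% fit$beta) + fit$b) -
                      as.numeric(predict(ref, toy$x)))), 1e-4)
})

test_that("KKT conditions hold after any fit", {
  toy <- svr_toy(40, seed = 4)
  cfg <- svr_config(cv_folds = 2, gamma_scale = "none",
                    C_grid = 10, gamma_grid = 1, epsilon_grid = 0.2)
  fit <- fit_svr(toy$x, toy$y, cfg, seed = 2)
  expect_true(all(abs(fit$dual_coef) <= fit$C + 1e-8)) # box constraint
  expect_lt(abs(sum(fit$dual_coef)), 1e-8)             # balance constraint
  # non-support training points sit inside the epsilon tube
  pred <- predict(fit, toy$x)
  sv_rows <- apply(toy$x, 1, function(r) {
    any(apply(fit$support_vectors, 1, function(s) all(s == r)))
  })
  if (any(!sv_rows)) {
    expect_true(all(abs(pred[!sv_rows] - toy$y[!sv_rows]) <= fit$epsilon + 1e-6))
  }
  # prediction on a support vector equals the explicit kernel summation
  Zsv <- cuffbp:::apply_scaler(fit$support_vectors, fit$scaler)
  z1 <- cuffbp:::apply_scaler(fit$support_vectors[1, , drop = FALSE], fit$scaler)
  manual <- sum(vapply(seq_len(nrow(Zsv)), function(i) {
    fit$dual_coef[i] * rbf_kernel(Zsv[i, ], z1[1, ], fit$gamma)
  }, numeric(1))) + fit$bias
  expect_equal(predict(fit, fit$support_vectors[1, , drop = FALSE]), manual)
})

test_that("raising epsilon never increases the support-vector count", {
  toy <- svr_toy(40, seed = 5)
  K <- exp(-1 * as.matrix(dist(toy$x))^2)
  nsv <- sapply(c(0.01, 0.1, 0.5, 1, 2), function(eps) {
    f <- cuffbp:::svr_smo_cpp(K, toy$y, C = 10, eps = eps, tol = 1e-6)
    sum(abs(f$beta) > 1e-12)
  })
  expect_true(all(diff(nsv) <= 0))
})

test_that("grid search reports every grid point and groups folds by subject", {
  set.seed(9)
  n <- 80
  x <- cbind(rnorm(n), rnorm(n))
  y <- 110 + 8 * x[, 1] + rnorm(n, 0, 0.5)
  subj <- rep(sprintf("S%02d", 1:20), each = 4)
  cfg <- svr_config(cv_folds = 10)
  fit <- fit_svr(x, y, cfg, seed = 3, subject_ids = subj, target_name = "SBP")
  expect_equal(nrow(fit$cv_report), 2 * 2 * 3) # {10,100} x {10,100} x 3 eps
  expect_true(all(is.finite(fit$cv_report$mae)))
  folds <- cuffbp:::make_folds(n, 10, seed = 3, subject_ids = subj)
  expect_true(all(tapply(folds, subj, function(f) length(unique(f))) == 1))
  expect_error(predict(fit, cbind(1, 2, 3)), "dimension")
  expect_error(fit_svr(matrix(1, 30, 2), rnorm(30), cfg, 1), "degenerate")
})
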