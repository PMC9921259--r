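# Independent oracles used to cross-check the implementation. These stay
# deliberately naive: direct formulas, dense solvers and brute-force scans,
# never the code paths they validate.

# Power of a signal inside a frequency band, from the raw periodogram.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(fft(x - mean(x)))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq >= lo & freq <= hi
  sum(sp[keep])
}

# Pulse-onset oracle: first sample at or after the R index where the (clean)
# PPG rises above a tiny threshold.
onset_after <- function(ppg, r_index, tol = 1e-9) {
  i <- r_index
  while (i <= length(ppg) && ppg[i] <= tol) i <- i + 1L
  if (i > length(ppg)) NA_integer_ else i
}

# Dual objective of epsilon-SVR in the beta parametrization:
# 1/2 b'Kb + eps * sum|b| - y'b (equals the [alpha, alpha*] objective at any
# complementary decomposition).
svr_dual_objective <- function(beta, K, y, eps) {
  0.5 * sum(beta * (K %*% beta)) + eps * sum(abs(beta)) - sum(y * beta)
}

# Dense quadratic-programming oracle for the epsilon-SVR dual, solved with
# kernlab's interior-point QP over z = [alpha; alpha*] in [0, C]^{2n} with
# sum(alpha) - sum(alpha*) = 0. Independent of the package's SMO solver.
svr_qp_oracle <- function(K, y, C, eps, ridge = 1e-8) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(ridge, 2 * n)
  cvec <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), nrow = 1)
  sol <- kernlab::ipop(c = cvec, H = H, A = A, b = 0,
                       l = rep(0, 2 * n), u = rep(C, 2 * n), r = 0,
                       sigf = 9, maxiter = 200)
  z <- kernlab::primal(sol)
  beta <- z[1:n] - z[(n + 1):(2 * n)]
  # bias from strictly-inside variables, as KKT prescribes
  G <- c(K %*% beta, -(K %*% beta)) + cvec
  q <- c(rep(1, n), rep(-1, n))
  free <- z > 1e-6 * C & z < C * (1 - 1e-6)
  b <- if (any(free)) mean((-q * G)[free]) else 0
  list(beta = beta, b = b,
       objective = svr_dual_objective(beta, K, y, eps))
}

# Brute-force error metrics recomputation.
metrics_bruteforce <- function(est, act) {
  e <- est - act
  n <- length(e)
  me <- sum(e) / n
  list(rmse = sqrt(sum(e^2) / n),
       mae = sum(abs(e)) / n,
       std_err = sqrt(sum((e - me)^2) / (n - 1)),
       me = me)
}
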