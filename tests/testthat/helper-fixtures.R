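# Shared fixtures: small deterministic profiles and cohorts built in code.

# A noiseless 60-bpm subject with zero jitter: every protocol count is exact.
quiet_profile <- function(subject_id = "S001", heart_rate = 60, seed = 7,
                          ...) {
  subject_profile(subject_id, heart_rate = heart_rate, rr_jitter_sd = 0,
                  noise_sd = 0, drift_amp = 0, bp_noise_sd = 0, ptt_sd = 0,
                  seed = seed, ...)
}

# A tiny CNN (2 channels per block) for gradient checks and shape tests.
tiny_cnn_config <- function() {
  cnn_config(channels = c(2, 2, 2, 2, 2), kernel_len = 3)
}

tmp_file <- function(ext = "") tempfile(fileext = ext)

tmp_dir <- function() {
  d <- tempfile()
  dir.create(d)
  d
}

# Small regression toy set for SVR tests: smooth 1-D function, n <= 50.
svr_toy <- function(n = 30, seed = 2, noise = 1) {
  set.seed(seed)
  x <- matrix(sort(runif(n, -2, 2)), ncol = 1)
  y <- 120 + 15 * sin(1.5 * x[, 1]) + rnorm(n, 0, noise)
  list(x = x, y = y)
}
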