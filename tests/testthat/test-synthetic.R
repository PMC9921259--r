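# Synthetic waveform generator: beat grids, PTT-delayed pulses, inverse
# PTT-to-BP coupling, determinism and physiological range conservation.

test_that("beat counts and sample counts follow rate and duration exactly", {
  p <- quiet_profile()
  e <- generate_ecg(p, duration = 60)
  expect_length(e$r_times, 60) # 60 bpm x 60 s, zero jitter
  expect_length(generate_ecg(p, duration = 1)$ecg, 125)
  expect_error(generate_ecg(p, duration = 0), "duration")

  pj <- subject_profile("S9", heart_rate = 75, rr_jitter_sd = 0.02,
                        noise_sd = 0, drift_amp = 0, seed = 5)
  ej <- generate_ecg(pj, duration = 420)
  expect_lte(abs(length(ej$r_times) - 525), 3)
})

test_that("normalized ECG has its per-beat maximum at the R-peak, above 0.5", {
  p <- quiet_profile()
  e <- generate_ecg(p, duration = 30)
  norm <- normalize_minmax(e$ecg)
  for (k in seq_along(e$r_times)) {
    lo <- max(1, e$r_times[k] - 62)
    hi <- min(length(norm), e$r_times[k] + 62)
    expect_lte(abs(which.max(norm[lo:hi]) + lo - 1 - e$r_times[k]), 1)
    expect_gt(norm[e$r_times[k]], 0.5)
  }
})

test_that("PPG pulse onset lands exactly round(ptt * fs) samples after R", {
  # single beat: R at sample 1 (the record start), ptt 0.2 s -> onset 25
  # samples later
  ppg <- generate_ppg(r_times = 1L, ptt_per_beat = 0.2, length = 200)
  expect_equal(onset_after(ppg, 1L), 1L + 25L)
  expect_true(all(ppg[1:25] == 0))

  # ptt = 0: onset coincides with the R sample
  ppg0 <- generate_ppg(r_times = 10L, ptt_per_beat = 0, length = 200)
  expect_equal(onset_after(ppg0, 1L), 10L)

  # 420 beats at constant ptt 0.24 s: measured lag is 30 samples for all
  p <- quiet_profile()
  e <- generate_ecg(p, duration = 420)
  ppg3 <- generate_ppg(e$r_times, 0.24, length(e$ecg))
  lags <- vapply(e$r_times, function(r) onset_after(ppg3, r) - r, integer(1))
  expect_true(all(lags == 30L))
})

test_that("an over-long pulse is truncated and flagged", {
  # pulse support is 75 samples; the second beat's pulse runs past sample 300
  ppg <- generate_ppg(r_times = c(10L, 290L), ptt_per_beat = 0.2, length = 300)
  expect_equal(attr(ppg, "truncated_beats"), 2L)
  full <- generate_ppg(r_times = 10L, ptt_per_beat = 0.2, length = 300)
  expect_length(attr(full, "truncated_beats"), 0)
  expect_error(generate_ppg(5L, -0.1, 100), "non-negative")
  expect_error(generate_ppg(500L, 0.2, 100), "within the record")
})

test_that("BP labels follow the calibrated inverse PTT law", {
  p <- quiet_profile(ptt_base = 0.25)
  bp <- generate_bp(p, 0.25)
  expect_equal(bp$sbp, p$sbp_base)
  expect_equal(bp$dbp, p$dbp_base)
  # halving PTT raises SBP strictly
  expect_gt(generate_bp(p, 0.125)$sbp, bp$sbp)
  # hand computation: a = 0, b = 40 -> SBP at ptt 0.25 is 160
  p40 <- quiet_profile(ptt_base = 0.25, sbp_base = 160, slope_sbp = 40)
  expect_equal(unname(generate_bp(p40, 0.25)$coef["a_s"]), 0)
  expect_equal(generate_bp(p40, 0.25)$sbp, 160)

  # zero-noise coupling is a perfect inverse relationship
  ptt <- seq(0.15, 0.35, length.out = 50)
  bp2 <- generate_bp(p, ptt)
  expect_equal(cor(ptt, bp2$sbp, method = "spearman"), -1)
  expect_true(all(diff(bp2$sbp[order(ptt)]) < 0))
})

test_that("generation is bit-identical under a fixed profile and seed", {
  p <- subject_profile("S1", seed = 42)
  r1 <- generate_record(p, duration = 20)
  r2 <- generate_record(p, duration = 20)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$sbp, r2$sbp)

  c1 <- generate_cohort(3, duration = 15, seed = 9)
  c2 <- generate_cohort(3, duration = 15, seed = 9)
  expect_identical(c1, c2)
})

test_that("cohorts have stated shapes and conserve physiological ranges", {
  cohort <- generate_cohort(4, duration = 420, seed = 3)
  expect_length(cohort, 4)
  for (rec in cohort) {
    expect_equal(rec$length, 52500) # 420 s x 125 Hz
    expect_equal(length(rec$sbp), length(rec$r_times))
    expect_equal(length(rec$dbp), length(rec$r_times))
    expect_true(all(rec$sbp >= 80 & rec$sbp <= 200))
    expect_true(all(rec$dbp >= 40 & rec$dbp <= 120))
    expect_true(all(rec$sbp > rec$dbp))
  }
  expect_length(generate_cohort(1, duration = 10, seed = 1), 1)
  expect_error(generate_cohort(0, duration = 10), "n_subjects")
})
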