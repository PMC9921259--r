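# R-peak detection by thresholding with minimum peak distance, R-centered
# one-second beat windows, and nearest-label beat annotation.

test_that("detection recovers the simulator's R-peaks on a clean record", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 60)
  pre <- preprocess_record(rec)
  peaks <- detect_r_peaks(pre$channels[["ECG_norm"]])
  expect_length(peaks, length(rec$r_times))
  expect_true(all(abs(peaks - rec$r_times) <= 2))
})

test_that("min-distance suppression keeps the taller conflicting peak", {
  x <- numeric(300)
  x[100] <- 0.8
  x[150] <- 0.9 # 50 samples apart: conflict, taller wins
  expect_equal(detect_r_peaks(x, peak_config()), 150L)
  # equal amplitudes: the earlier peak wins deterministically
  x2 <- numeric(300)
  x2[100] <- 0.8
  x2[150] <- 0.8
  expect_equal(detect_r_peaks(x2, peak_config()), 100L)
  # spacing exactly min_distance is allowed
  x3 <- numeric(400)
  x3[c(100, 225, 350)] <- 0.9
  expect_equal(detect_r_peaks(x3, peak_config()), c(100L, 225L, 350L))
})

test_that("sub-threshold signals and empty input give no peaks", {
  expect_length(detect_r_peaks(rep(0.4, 1000) * sin(1:1000)), 0)
  expect_length(detect_r_peaks(numeric(0)), 0)
})

test_that("beat windows are truncated or zero-padded to 125 with R at 63", {
  set.seed(8)
  ecg <- runif(2000, 0.1, 0.4)
  ppg <- runif(2000)
  # 60 bpm: RR = 125 -> the window is the untouched cycle
  r60 <- seq(200L, 1600L, by = 125L)
  ecg[r60] <- 1
  b60 <- segment_beats(ecg, ppg, r60)
  k <- 3
  expect_equal(b60$ecg_beats[k, ], ecg[(r60[k] - 62):(r60[k] + 62)])
  expect_true(all(apply(b60$ecg_beats, 1, which.max) == 63))

  # 100 bpm: RR = 75 -> 25 zeros padded on each side of the cycle
  r100 <- seq(200L, 1400L, by = 75L)
  b100 <- segment_beats(ecg, ppg, r100)
  mid <- b100$ecg_beats[5, ]
  expect_equal(mid[1:25], rep(0, 25))
  expect_equal(mid[101:125], rep(0, 25))
  expect_equal(mid[26:100], ecg[(r100[5] - 37):(r100[5] + 37)])

  # R near the record start: left side zero-padded up to the center
  bedge <- segment_beats(ecg, ppg, c(11L, 300L))
  expect_equal(bedge$ecg_beats[1, 1:52], rep(0, 52))
  expect_equal(bedge$ecg_beats[1, 53], ecg[1])

  expect_warning(segment_beats(ecg, ppg, c(100L, 5000L)), "out-of-range")
})

test_that("beats take the nearest label; far-off beats are dropped", {
  beats <- list(ecg_beats = matrix(0, 4, 125), ppg_beats = matrix(0, 4, 125),
                r_index = c(1L, 3751L, 7501L, 11251L)) # 0, 30, 60, 90 s
  # labels exactly at R times: all labeled, none dropped
  lab <- label_beats(beats, c(120, 125, 130, 135), c(80, 82, 84, 86),
                     label_times = c(0, 30, 60, 90))
  expect_equal(lab$sbp, c(120, 125, 130, 135))
  expect_equal(lab$n_dropped, 0)

  # a single label is shared by every beat in range
  lab1 <- label_beats(beats, 122, 81, label_times = 30, max_gap = 100)
  expect_equal(lab1$sbp, rep(122, 4))

  # minute-grid labels: the 30-s beat ties between 0 s and 60 s; earlier wins
  lab2 <- label_beats(beats, c(120, 130), c(80, 84), label_times = c(0, 60))
  expect_equal(lab2$sbp, c(120, 120, 130, 130))

  # labels further than 30 s are dropped and counted
  lab3 <- label_beats(beats, 140, 90, label_times = 200)
  expect_equal(nrow(lab3$ecg_beats), 0)
  expect_equal(lab3$n_dropped, 4)
  expect_error(label_beats(beats, numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("a 7-minute 60-bpm record yields exactly 420 centered beats", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 420)
  pre <- preprocess_record(rec)
  beats <- segment_record(pre)
  peaks <- detect_r_peaks(pre$channels[["ECG_norm"]])
  expect_equal(nrow(beats$ecg_beats), 420)
  expect_equal(nrow(beats$ecg_beats) + beats$n_dropped, length(peaks))
  expect_true(all(apply(beats$ecg_beats, 1, which.max) == 63))
  expect_true(all(beats$sbp > beats$dbp))
})
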