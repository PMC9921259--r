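# Record container, CSV/WFDB round trips and the collection-window protocol.

test_that("training CSV export round-trips the four channels", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 5)
  path <- tmp_file(".csv")
  export_training_csv(rec, path)
  back <- read_record(path)
  expect_named(back$channels, c("ECG", "PLETH", "ABP Sys", "ABP Dias"))
  expect_equal(back$channels[["ECG"]], rec$channels[["ECG"]], tolerance = 1e-12)
  expect_equal(back$channels[["ABP Sys"]], rec$channels[["ABP Sys"]],
               tolerance = 1e-12)
  expect_equal(back$length, rec$length)
})

test_that("requesting an absent channel names it in the error", {
  rec <- bp_record(list(II = sin(1:100), PLETH = cos(1:100)), fs = 125)
  path <- tmp_file(".csv")
  write.csv(data.frame(II = rec$channels$II, PLETH = rec$channels$PLETH),
            path, row.names = FALSE)
  expect_error(read_record(path, channel_names = "AVR"), "AVR")
  expect_equal(ecg_channel(rec), "II") # lead preference falls back past AVR
})

test_that("WFDB write-read round trip is exact to one quantization step", {
  p <- quiet_profile(seed = 11)
  rec <- generate_record(p, duration = 4)
  path <- file.path(tmp_dir(), "s001")
  write_record_wfdb(rec, path)
  back <- read_record(path)
  expect_equal(back$fs, 125)
  expect_named(back$channels, names(rec$channels))
  for (ch in names(rec$channels)) {
    x <- rec$channels[[ch]]
    step <- (max(x) - min(x)) / 60000
    if (step == 0) step <- 1e-12
    expect_lte(max(abs(back$channels[[ch]] - x)), step + 1e-12)
  }
})

test_that("collection windows concatenate to exactly n_windows x window_len", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 660) # the 11 minutes the protocol needs
  w <- extract_collection_windows(rec)
  expect_equal(w$length, 7 * 60 * 125)

  one <- extract_collection_windows(
    rec, collection_spec(skip_initial = 0, n_windows = 1, window_len = 60))
  expect_equal(one$channels[["ECG"]], rec$channels[["ECG"]][1:7500])

  short <- generate_record(p, duration = 600) # 10 min < the required 11
  expect_error(extract_collection_windows(short), "too short")
})

test_that("short NA runs are interpolated, long runs reject the window", {
  p <- quiet_profile()
  rec <- generate_record(p, duration = 660)
  ecg <- rec$channels[["ECG"]]
  ecg[10000:10010] <- NA # 11 samples < 0.2 s * 125 = 25
  rec$channels[["ECG"]] <- ecg
  w <- extract_collection_windows(rec)
  expect_false(anyNA(w$channels[["ECG"]]))

  ecg[20000:20100] <- NA # 101 samples > 25
  rec$channels[["ECG"]] <- ecg
  expect_error(extract_collection_windows(rec), "NA run")
})

test_that("container invariants are enforced and empty export warns", {
  expect_error(bp_record(list(a = 1:5, b = 1:4), fs = 125), "equal length")
  expect_error(bp_record(list(1:5), fs = 125), "named")
  rec <- bp_record(list(ECG = numeric(0), PLETH = numeric(0),
                        "ABP Sys" = numeric(0), "ABP Dias" = numeric(0)),
                   fs = 125)
  path <- tmp_file(".csv")
  expect_warning(export_training_csv(rec, path), "header-only")
  expect_equal(length(readLines(path)), 1)
})
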