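# Synthetic cardiovascular waveform simulator.
#
# Emulates the structure the estimation pipeline assumes in real ICU records:
# an ECG with an unambiguous dominant R-wave, a PPG pulse whose foot trails
# each R-peak by the pulse transit time (PTT), and per-beat SBP/DBP labels
# generated from an inverse PTT-to-BP relationship. PTT is a latent variable
# of the simulator only; it is never exposed to the estimator as a feature.

ECG_BUMPS <- list(
  # P, Q, R, S, T as Gaussian bumps; offsets/widths are fractions of the RR
  # interval, amplitudes in mV. R dominates so threshold detection at 0.5 of
  # the normalized range is unambiguous (T stays below ~0.45 after scaling).
  offset = c(p = -0.18, q = -0.04, r = 0.00, s = 0.04, t = 0.25),
  width  = c(p = 0.035, q = 0.015, r = 0.025, s = 0.015, t = 0.060),
  amp    = c(p = 0.12, q = -0.10, r = 1.00, s = -0.14, t = 0.30)
)

#' Subject profile for the waveform simulator
#'
#' Bundles the physiological and noise parameters that define one simulated
#' subject. Two generations from the same profile (same seed) are
#' bit-identical.
#'
#' @param subject_id Identifier string.
#' @param heart_rate Mean heart rate in beats/min, in `[40, 180]`.
#' @param ptt_base Baseline pulse transit time in seconds (> 0).
#' @param sbp_base,dbp_base Baseline systolic/diastolic pressure in mmHg at
#'   `ptt_base`; must satisfy `sbp_base > dbp_base` and lie in
#'   `[80, 200]` / `[40, 120]`.
#' @param ptt_sd Beat-to-beat PTT standard deviation in seconds (>= 0); the
#'   per-beat PTT is truncated below at 0.05 s.
#' @param bp_noise_sd Additive label noise SD in mmHg (>= 0).
#' @param rr_jitter_sd Relative SD of the RR interval (e.g. 0.02 = 2%).
#' @param noise_sd Additive waveform noise SD, in units of the R amplitude
#'   (ECG) / pulse amplitude (PPG).
#' @param drift_amp Amplitude (mV) of a low-frequency sinusoidal baseline
#'   drift added to the ECG; its frequency is drawn from `[0.15, 0.2]` Hz,
#'   the usual respiratory wander band. Zero disables drift.
#' @param slope_sbp,slope_dbp Inverse-coupling slopes b in `BP = a + b / PTT`,
#'   in mmHg·s.
#' @param seed Integer seed for all of this subject's random streams.
#' @return An object of class `bp_profile`.
#' @export
#' @examples
#' p <- subject_profile("S001", heart_rate = 60, seed = 1)
#' rec <- generate_record(p, duration = 10)
#' length(rec$r_times)
subject_profile <- function(subject_id = "S001",
                            heart_rate = 60,
                            ptt_base = 0.25,
                            sbp_base = NULL,
                            dbp_base = NULL,
                            ptt_sd = 0.015,
                            bp_noise_sd = 1,
                            rr_jitter_sd = 0.02,
                            noise_sd = 0.02,
                            drift_amp = 0.2,
                            slope_sbp = 30,
                            slope_dbp = 15,
                            seed = 1L) {
  check_number(heart_rate, "heart_rate", 40, 180)
  check_number(ptt_base, "ptt_base", 1e-6, Inf)
  if (is.null(sbp_base)) sbp_base <- slope_sbp / ptt_base
  if (is.null(dbp_base)) dbp_base <- slope_dbp / ptt_base
  check_number(sbp_base, "sbp_base", 80, 200)
  check_number(dbp_base, "dbp_base", 40, 120)
  if (sbp_base <= dbp_base) stop_cuffbp("sbp_base must exceed dbp_base")
  check_number(ptt_sd, "ptt_sd", 0, Inf)
  check_number(bp_noise_sd, "bp_noise_sd", 0, Inf)
  check_number(rr_jitter_sd, "rr_jitter_sd", 0, Inf)
  check_number(noise_sd, "noise_sd", 0, Inf)
  check_number(drift_amp, "drift_amp", 0, Inf)
  structure(
    list(subject_id = subject_id, heart_rate = heart_rate,
         ptt_base = ptt_base, sbp_base = sbp_base, dbp_base = dbp_base,
         ptt_sd = ptt_sd, bp_noise_sd = bp_noise_sd,
         rr_jitter_sd = rr_jitter_sd, noise_sd = noise_sd,
         drift_amp = drift_amp, slope_sbp = slope_sbp,
         slope_dbp = slope_dbp, seed = as.integer(seed)),
    class = "bp_profile"
  )
}

# Continuous-time beat grid: first R at half an RR interval, subsequent beats
# at jittered RR increments. Returns beat times (s) and the RR used per beat.
beat_times <- function(profile, duration) {
  rr_base <- 60 / profile$heart_rate
  n_max <- ceiling(duration / rr_base) + 10L
  jit <- if (profile$rr_jitter_sd > 0) {
    with_seed(derive_seed(profile$seed, "rr"),
              rnorm(n_max, 0, profile$rr_jitter_sd))
  } else {
    numeric(n_max)
  }
  rr <- pmax(rr_base * (1 + jit), 0.3)
  t_beat <- rr_base / 2 + c(0, cumsum(rr[-length(rr)]))
  keep <- t_beat <= duration - 1 / 125 # last sample is (n-1)/fs
  list(t = t_beat[keep], rr = rr[keep])
}

#' Generate a synthetic ECG with known R-peak locations
#'
#' Builds each beat as a sum of five Gaussian bumps (P, Q, R, S, T) with
#' fixed relative timings and widths scaled by the RR interval, repeated at
#' (optionally jittered) RR increments, then adds measurement noise and the
#' profile's low-frequency baseline drift.
#'
#' @param profile A [subject_profile()].
#' @param duration Record duration in seconds (> 0).
#' @param fs Sampling frequency in Hz.
#' @return A list with elements `ecg` (numeric, `round(duration * fs)`
#'   samples, mV), `r_times` (1-based sample indices of the true R-peaks),
#'   `t_beat` (continuous beat times, s), `rr` (per-beat RR, s), `fs`.
#' @export
generate_ecg <- function(profile, duration, fs = 125) {
  check_number(duration, "duration", 1e-9, Inf)
  n <- round(duration * fs)
  bt <- beat_times(profile, duration)
  ecg <- numeric(n)
  for (k in seq_along(bt$t)) {
    tk <- bt$t[k]
    rrk <- bt$rr[k]
    i0 <- max(1L, floor((tk - 0.45 * rrk) * fs) + 1L)
    i1 <- min(n, ceiling((tk + 0.60 * rrk) * fs) + 1L)
    if (i0 > i1) next
    tt <- (seq.int(i0, i1) - 1) / fs - tk
    for (j in seq_along(ECG_BUMPS$amp)) {
      ecg[i0:i1] <- ecg[i0:i1] + ECG_BUMPS$amp[j] *
        exp(-0.5 * ((tt - ECG_BUMPS$offset[j] * rrk) / (ECG_BUMPS$width[j] * rrk))^2)
    }
  }
  if (profile$drift_amp > 0) {
    dr <- with_seed(derive_seed(profile$seed, "drift"),
                    c(runif(1, 0.15, 0.20), runif(1, 0, 2 * pi)))
    tim <- (seq_len(n) - 1) / fs
    ecg <- ecg + profile$drift_amp * sin(2 * pi * dr[1] * tim + dr[2])
  }
  if (profile$noise_sd > 0) {
    ecg <- ecg + with_seed(derive_seed(profile$seed, "ecg-noise"),
                           rnorm(n, 0, profile$noise_sd))
  }
  list(ecg = ecg, r_times = as.integer(round(bt$t * fs)) + 1L,
       t_beat = bt$t, rr = bt$rr, fs = fs)
}

#' Generate a PPG waveform from R-peak times and per-beat PTT
#'
#' Places one skewed smooth pulse (a gamma-like bump rising from zero) per
#' beat, with the pulse foot exactly `round(ptt * fs)` samples after the
#' corresponding R-peak.
#'
#' @param r_times 1-based R-peak sample indices, all within the record.
#' @param ptt_per_beat Positive PTT in seconds, one value per beat (recycled
#'   if scalar).
#' @param length Output length in samples.
#' @param fs Sampling frequency in Hz.
#' @param time_to_peak Pulse upstroke duration in seconds.
#' @param pulse_len Pulse support in seconds.
#' @return Numeric waveform of `length` samples with attribute
#'   `"truncated_beats"`: indices of beats whose pulse ran past the record end
#'   and was truncated (empty integer vector when none).
#' @export
generate_ppg <- function(r_times, ptt_per_beat, length, fs = 125,
                         time_to_peak = 0.15, pulse_len = 0.6) {
  ptt <- rep_len(ptt_per_beat, base::length(r_times))
  if (any(ptt < 0)) stop_cuffbp("PTT values must be non-negative")
  if (any(r_times < 1 | r_times > length)) {
    stop_cuffbp("all r_times must lie within the record")
  }
  m <- round(pulse_len * fs)
  tau <- seq_len(m) / fs # the onset sample already carries the first rise
  shape <- (tau / time_to_peak)^2 * exp(2 - 2 * tau / time_to_peak)
  ppg <- numeric(length)
  truncated <- integer(0)
  for (k in seq_along(r_times)) {
    onset <- r_times[k] + round(ptt[k] * fs)
    if (onset + m - 1L > length) truncated <- c(truncated, k)
    if (onset > length) next
    idx <- onset:min(length, onset + m - 1L)
    ppg[idx] <- ppg[idx] + shape[seq_along(idx)]
  }
  attr(ppg, "truncated_beats") <- truncated
  ppg
}

#' Generate per-beat SBP/DBP labels from PTT via an inverse coupling
#'
#' Implements `BP_i = a + b / ptt_i + noise` per target, with `(a, b)`
#' calibrated per subject so that `ptt_base` maps exactly to
#' `(sbp_base, dbp_base)`. Noise-free series are strictly decreasing in PTT.
#' Noisy values are clipped to physiological ranges (SBP in `[80, 200]`,
#' DBP in `[40, 120]`) and DBP is kept strictly below SBP.
#'
#' @param profile A [subject_profile()].
#' @param ptt_per_beat Positive per-beat PTT values in seconds.
#' @return A list with `sbp`, `dbp` (mmHg, one per beat) and `coef`
#'   (`a_s`, `b_s`, `a_d`, `b_d`).
#' @export
generate_bp <- function(profile, ptt_per_beat) {
  if (any(ptt_per_beat <= 0)) stop_cuffbp("all PTT values must be positive")
  b_s <- profile$slope_sbp
  b_d <- profile$slope_dbp
  a_s <- profile$sbp_base - b_s / profile$ptt_base
  a_d <- profile$dbp_base - b_d / profile$ptt_base
  sbp <- a_s + b_s / ptt_per_beat
  dbp <- a_d + b_d / ptt_per_beat
  if (profile$bp_noise_sd > 0) {
    noise <- with_seed(derive_seed(profile$seed, "bp-noise"),
                       matrix(rnorm(2 * length(sbp), 0, profile$bp_noise_sd), nrow = 2))
    sbp <- sbp + noise[1, ]
    dbp <- dbp + noise[2, ]
  }
  sbp <- pmin(pmax(sbp, 80), 200)
  dbp <- pmin(pmax(dbp, 40), 120)
  dbp <- pmin(dbp, sbp - 1)
  list(sbp = sbp, dbp = dbp, coef = c(a_s = a_s, b_s = b_s, a_d = a_d, b_d = b_d))
}

#' Generate one complete synthetic subject record
#'
#' Combines [generate_ecg()], a per-beat latent PTT stream, [generate_ppg()]
#' and [generate_bp()] into a waveform record carrying the four channels the
#' pipeline consumes (`ECG`, `PLETH`, `ABP Sys`, `ABP Dias`; the per-beat BP
#' labels are expanded to per-sample step series for the label channels) plus
#' ground-truth beat metadata.
#'
#' @inheritParams generate_ecg
#' @return A [bp_record()] with extra fields `r_times` (true R sample
#'   indices), `sbp`, `dbp` (per-beat labels), `label_times` (label times, s)
#'   and `ptt` (latent per-beat PTT, s).
#' @export
generate_record <- function(profile, duration = 420, fs = 125) {
  e <- generate_ecg(profile, duration, fs)
  n <- length(e$ecg)
  n_beat <- length(e$r_times)
  ptt <- profile$ptt_base + if (profile$ptt_sd > 0) {
    with_seed(derive_seed(profile$seed, "ptt"), rnorm(n_beat, 0, profile$ptt_sd))
  } else {
    numeric(n_beat)
  }
  ptt <- pmax(ptt, 0.05)
  ppg <- generate_ppg(e$r_times, ptt, n, fs)
  if (profile$noise_sd > 0) {
    ppg <- ppg + with_seed(derive_seed(profile$seed, "ppg-noise"),
                           rnorm(n, 0, profile$noise_sd))
  }
  bp <- generate_bp(profile, ptt)
  # Per-sample step channels: each sample takes the label of the beat whose
  # RR-midpoint interval contains it.
  bounds <- if (n_beat > 1) {
    round((e$r_times[-n_beat] + e$r_times[-1]) / 2)
  } else {
    integer(0)
  }
  beat_of_sample <- findInterval(seq_len(n), c(1L, bounds + 1L))
  rec <- bp_record(
    channels = list(
      "ECG" = e$ecg,
      "PLETH" = as.numeric(ppg),
      "ABP Sys" = bp$sbp[beat_of_sample],
      "ABP Dias" = bp$dbp[beat_of_sample]
    ),
    fs = fs,
    source_id = profile$subject_id
  )
  rec$r_times <- e$r_times
  rec$sbp <- bp$sbp
  rec$dbp <- bp$dbp
  rec$label_times <- (e$r_times - 1) / fs
  rec$ptt <- ptt
  rec$profile <- profile
  rec
}

#' Generate a cohort of synthetic subjects
#'
#' Subject profiles are drawn from physiological ranges; the subject baseline
#' pressures follow a cohort-level inverse law (`SBP = 30 / PTT`,
#' `DBP = 15 / PTT`, mmHg with PTT in s) plus a small subject-specific offset,
#' so that between-subject BP differences remain predictable from the
#' waveforms in a calibration-free setting. All randomness flows from a single
#' cohort seed through per-subject substreams, so cohorts are reproducible.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param duration Duration per subject in seconds.
#' @param seed Cohort seed.
#' @param hr_range Heart-rate range (beats/min) subjects are drawn from.
#' @param ptt_range Baseline PTT range (s).
#' @param subject_sd_sbp,subject_sd_dbp SD (mmHg) of the subject-level offset
#'   around the cohort inverse law.
#' @param ptt_sd,bp_noise_sd,rr_jitter_sd,noise_sd,drift_amp Per-subject noise
#'   parameters passed to [subject_profile()].
#' @param fs Sampling frequency in Hz.
#' @return A list of [generate_record()] outputs, one per subject.
#' @export
#' @examples
#' cohort <- generate_cohort(2, duration = 20, seed = 42)
#' sapply(cohort, function(r) r$source_id)
generate_cohort <- function(n_subjects, duration = 420, seed = 1L,
                            hr_range = c(55, 65), ptt_range = c(0.20, 0.32),
                            subject_sd_sbp = 2, subject_sd_dbp = 1.5,
                            ptt_sd = 0.015, bp_noise_sd = 1,
                            rr_jitter_sd = 0.02, noise_sd = 0.02,
                            drift_amp = 0.2, fs = 125) {
  if (n_subjects < 1) stop_cuffbp("n_subjects must be >= 1")
  draws <- with_seed(derive_seed(seed, "cohort"), {
    data.frame(
      hr = runif(n_subjects, hr_range[1], hr_range[2]),
      ptt = runif(n_subjects, ptt_range[1], ptt_range[2]),
      off_s = rnorm(n_subjects, 0, subject_sd_sbp),
      off_d = rnorm(n_subjects, 0, subject_sd_dbp)
    )
  })
  lapply(seq_len(n_subjects), function(i) {
    prof <- subject_profile(
      subject_id = sprintf("S%03d", i),
      heart_rate = draws$hr[i],
      ptt_base = draws$ptt[i],
      sbp_base = 30 / draws$ptt[i] + draws$off_s[i],
      dbp_base = 15 / draws$ptt[i] + draws$off_d[i],
      ptt_sd = ptt_sd, bp_noise_sd = bp_noise_sd,
      rr_jitter_sd = rr_jitter_sd, noise_sd = noise_sd,
      drift_amp = drift_amp,
      seed = derive_seed(seed, "subject", i)
    )
    generate_record(prof, duration = duration, fs = fs)
  })
}
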