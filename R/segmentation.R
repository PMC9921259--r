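# R-peak detection by amplitude thresholding with a minimum peak distance,
# and R-centered fixed-length (one-second) beat windowing of ECG and PPG.

#' Peak-detection configuration
#'
#' The 0.5 threshold applies to the min-max-normalized ECG (the signal is
#' normalized to its value range before detection), and the default minimum
#' peak distance of 125 samples corresponds to one cardiac cycle at 60 BPM
#' and 125 Hz.
#'
#' @param threshold Normalized amplitude threshold in (0, 1).
#' @param min_distance Minimum distance between kept peaks, in samples.
#' @return An object of class `bp_peak_config`.
#' @export
peak_config <- function(threshold = 0.5, min_distance = 125L) {
  check_number(threshold, "threshold", 1e-12, 1 - 1e-12)
  check_number(min_distance, "min_distance", 1, Inf)
  structure(list(threshold = threshold, min_distance = as.integer(min_distance)),
            class = "bp_peak_config")
}

#' Detect ECG R-peaks by thresholding
#'
#' Finds local maxima above the threshold, then suppresses conflicts closer
#' than `min_distance` samples by keeping the larger-amplitude peak
#' (ties keep the earlier peak). Kept peaks are at least `min_distance`
#' samples apart.
#'
#' @param ecg_normalized ECG normalized to `[0, 1]`.
#' @param config A [peak_config()].
#' @return Strictly increasing 1-based sample indices of the kept R-peaks.
#' @export
detect_r_peaks <- function(ecg_normalized, config = peak_config()) {
  x <- ecg_normalized
  n <- length(x)
  if (n < 3) return(integer(0))
  # local maxima: strictly above the left neighbour, not below the right
  # (the leftmost sample of a plateau wins)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > config$threshold]
  if (!length(cand)) return(integer(0))
  # greedy suppression: visit by descending amplitude (earlier index wins
  # ties), keep a candidate only if it is >= min_distance from every kept one
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= config$min_distance)) {
      kept <- c(kept, p)
    }
  }
  sort(kept)
}

#' Cut R-centered one-beat windows from ECG and PPG
#'
#' Each beat covers one cardiac cycle, bounded by the midpoints to the
#' neighbouring R-peaks (first/last beats mirror their one available side).
#' The cycle is symmetrically truncated (when longer than `round(fs)` samples,
#' i.e. heart rate below 60 BPM at 125 Hz) or symmetrically zero-padded (when
#' shorter, rate above 60 BPM) so every window has exactly `round(fs)` samples
#' with the R-peak at the central position (sample 63 of 125). Windows running
#' past the record edges are zero-padded.
#'
#' @param ecg,ppg Equal-length numeric vectors (normalized).
#' @param r_indices 1-based R-peak sample indices.
#' @param fs Sampling frequency in Hz; the window length is `round(fs * 1 s)`.
#' @return A list with `ecg_beats`, `ppg_beats` (matrices, one row per beat)
#'   and `r_index` (the source R sample of each row). Out-of-range R indices
#'   are skipped with a warning.
#' @export
segment_beats <- function(ecg, ppg, r_indices, fs = 125) {
  stopifnot(length(ecg) == length(ppg))
  n <- length(ecg)
  wlen <- round(fs)
  half <- (wlen - 1L) %/% 2L # 62 samples each side of the central R
  bad <- r_indices < 1L | r_indices > n
  if (any(bad)) {
    warning(sprintf("skipping %d out-of-range R index(es)", sum(bad)), call. = FALSE)
    r_indices <- r_indices[!bad]
  }
  nb <- length(r_indices)
  ecg_beats <- matrix(0, nrow = nb, ncol = wlen)
  ppg_beats <- matrix(0, nrow = nb, ncol = wlen)
  for (k in seq_len(nb)) {
    r <- r_indices[k]
    lh <- if (k > 1) (r - r_indices[k - 1]) %/% 2L else NA_integer_
    rh <- if (k < nb) (r_indices[k + 1] - r) %/% 2L else NA_integer_
    if (is.na(lh)) lh <- if (is.na(rh)) half else rh # one-sided midpoints
    if (is.na(rh)) rh <- lh
    left <- min(half, lh, r - 1L)
    right <- min(wlen - 1L - half, rh, n - r)
    ecg_beats[k, (half + 1L - left):(half + 1L + right)] <- ecg[(r - left):(r + right)]
    ppg_beats[k, (half + 1L - left):(half + 1L + right)] <- ppg[(r - left):(r + right)]
  }
  list(ecg_beats = ecg_beats, ppg_beats = ppg_beats, r_index = r_indices)
}

#' Attach SBP/DBP labels to segmented beats
#'
#' Each beat takes the label whose timestamp is nearest its R time (ties go
#' to the earlier label). Beats with no label within `max_gap` seconds are
#' dropped and counted.
#'
#' @param beats Output of [segment_beats()].
#' @param sbp_series,dbp_series Label values in mmHg.
#' @param label_times Label timestamps in seconds (non-empty, same length as
#'   the label series).
#' @param fs Sampling frequency used to convert R indices to seconds.
#' @param max_gap Maximum allowed |R time - label time| in seconds.
#' @param subject_id Identifier stored with every beat.
#' @return A list of class `bp_beats`: `ecg_beats`, `ppg_beats`, `r_index`,
#'   `sbp`, `dbp`, `subject_id`, `n_dropped`.
#' @export
label_beats <- function(beats, sbp_series, dbp_series, label_times,
                        fs = 125, max_gap = 30, subject_id = "record") {
  if (!length(label_times)) stop_cuffbp("label series is empty")
  stopifnot(length(sbp_series) == length(label_times),
            length(dbp_series) == length(label_times))
  r_time <- (beats$r_index - 1) / fs
  # nearest label; on a tie the earlier label wins
  nearest <- vapply(r_time, function(t) {
    d <- abs(label_times - t)
    which(d == min(d))[1]
  }, integer(1))
  gap <- abs(label_times[nearest] - r_time)
  keep <- gap <= max_gap
  structure(list(
    ecg_beats = beats$ecg_beats[keep, , drop = FALSE],
    ppg_beats = beats$ppg_beats[keep, , drop = FALSE],
    r_index = beats$r_index[keep],
    sbp = sbp_series[nearest[keep]],
    dbp = dbp_series[nearest[keep]],
    subject_id = rep(subject_id, sum(keep)),
    n_dropped = sum(!keep)
  ), class = "bp_beats")
}

#' Segment one preprocessed record into labelled beats
#'
#' Convenience wrapper: detects R-peaks on the normalized ECG, cuts beat
#' windows from the normalized ECG and PPG, and attaches the record's BP
#' labels. For synthetic records the per-beat label series and times are
#' taken from the generator's ground truth; for ingested records they are
#' read from the `ABP Sys` / `ABP Dias` step channels at the detected beats.
#'
#' @param record A preprocessed [bp_record()] (see [preprocess_record()]).
#' @param config A [peak_config()].
#' @return A `bp_beats` object.
#' @export
segment_record <- function(record, config = peak_config()) {
  ecg <- record$channels[["ECG_norm"]]
  ppg <- record$channels[["PLETH_norm"]]
  if (is.null(ecg) || is.null(ppg)) {
    stop_cuffbp("record has no normalized channels; run preprocess_record() first")
  }
  peaks <- detect_r_peaks(ecg, config)
  beats <- segment_beats(ecg, ppg, peaks, record$fs)
  if (!is.null(record$sbp) && !is.null(record$label_times)) {
    label_beats(beats, record$sbp, record$dbp, record$label_times,
                fs = record$fs, subject_id = record$source_id)
  } else if (all(c("ABP Sys", "ABP Dias") %in% names(record$channels))) {
    label_beats(beats,
                record$channels[["ABP Sys"]][peaks],
                record$channels[["ABP Dias"]][peaks],
                (peaks - 1) / record$fs,
                fs = record$fs, subject_id = record$source_id)
  } else {
    stop_cuffbp("record carries no BP labels")
  }
}

# Stack several bp_beats objects into one.
bind_beats <- function(beat_list) {
  structure(list(
    ecg_beats = do.call(rbind, lapply(beat_list, `[[`, "ecg_beats")),
    ppg_beats = do.call(rbind, lapply(beat_list, `[[`, "ppg_beats")),
    r_index = unlist(lapply(beat_list, `[[`, "r_index")),
    sbp = unlist(lapply(beat_list, `[[`, "sbp")),
    dbp = unlist(lapply(beat_list, `[[`, "dbp")),
    subject_id = unlist(lapply(beat_list, `[[`, "subject_id")),
    n_dropped = sum(vapply(beat_list, `[[`, numeric(1), "n_dropped"))
  ), class = "bp_beats")
}

#' @export
print.bp_beats <- function(x, ...) {
  cat(sprintf("<bp_beats: %d beats x %d samples, %d subject(s), %d dropped>\n",
              nrow(x$ecg_beats), ncol(x$ecg_beats),
              length(unique(x$subject_id)), x$n_dropped))
  invisible(x)
}
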