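# Waveform record container and I/O: labelled CSV matrices and a minimal
# WFDB (.hea/.dat, format 16) reader/writer, plus the collection protocol
# that keeps seven one-minute windows separated by 30-s gaps after skipping
# the first minute of a recording.

#' Waveform record container
#'
#' A named collection of equally long, uniformly sampled channels.
#'
#' @param channels Named list of equal-length numeric vectors. Downstream
#'   stages expect an ECG channel, `"PLETH"`, `"ABP Sys"` and `"ABP Dias"`.
#' @param fs Sampling frequency in Hz (> 0).
#' @param source_id Record identifier.
#' @return An object of class `bp_record`.
#' @export
bp_record <- function(channels, fs, source_id = "record") {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stop_cuffbp("`channels` must be a fully named list")
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) {
    stop_cuffbp("all channels must have equal length (got ",
                paste(unique(lens), collapse = ", "), ")")
  }
  check_number(fs, "fs", 1e-9, Inf)
  structure(list(channels = channels, fs = fs,
                 length = if (length(lens)) lens[[1]] else 0L,
                 source_id = source_id),
            class = "bp_record")
}

#' @export
print.bp_record <- function(x, ...) {
  cat(sprintf("<bp_record '%s': %d channels x %d samples @ %g Hz (%.1f s)>\n",
              x$source_id, length(x$channels), x$length, x$fs, x$length / x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# Preferred ECG lead order when an explicit lead is absent.
ECG_LEAD_ORDER <- c("AVR", "II", "I", "III", "V", "ECG")

#' Pick the ECG channel of a record
#'
#' Returns the first present channel in the preference order
#' AVR, II, I, III, V, ECG.
#'
#' @param record A [bp_record()].
#' @return The channel name.
#' @export
ecg_channel <- function(record) {
  hit <- ECG_LEAD_ORDER[ECG_LEAD_ORDER %in% names(record$channels)]
  if (!length(hit)) stop_cuffbp("record has no recognizable ECG channel (looked for ",
                                paste(ECG_LEAD_ORDER, collapse = ", "), ")")
  hit[1]
}

#' Read a waveform record from CSV or WFDB files
#'
#' CSV files must carry a header row of channel names, one sample per row.
#' WFDB records are read from a `.hea` header plus a format-16 `.dat` signal
#' file; the sampling frequency then comes from the header.
#'
#' @param path Path to a `.csv` file or to a WFDB record (with or without the
#'   `.hea` extension).
#' @param channel_names Channels to keep (default: all). A missing requested
#'   channel is an error naming it.
#' @param fs Sampling frequency for CSV input (ignored for WFDB). A rate
#'   other than 125 Hz triggers a warning; processing continues and the beat
#'   length is derived from `fs` downstream.
#' @return A [bp_record()].
#' @export
read_record <- function(path, channel_names = NULL, fs = 125) {
  is_wfdb <- grepl("\\.hea$", path) || file.exists(paste0(path, ".hea"))
  rec <- if (is_wfdb && !grepl("\\.csv$", path)) {
    read_record_wfdb(path)
  } else {
    if (!file.exists(path)) stop_cuffbp("file not found: ", path)
    df <- read.csv(path, check.names = FALSE)
    bp_record(as.list(df), fs = fs,
              source_id = sub("\\.csv$", "", basename(path)))
  }
  if (!is.null(channel_names)) {
    missing <- setdiff(channel_names, names(rec$channels))
    if (length(missing)) {
      stop_cuffbp("channel(s) not present in record: ",
                  paste(missing, collapse = ", "))
    }
    rec$channels <- rec$channels[channel_names]
  }
  if (rec$fs != 125) {
    warning(sprintf("sampling frequency is %g Hz, not 125 Hz; beat length will follow fs",
                    rec$fs), call. = FALSE)
  }
  rec
}

#' Write a record as WFDB header + format-16 signal files
#'
#' Signals are stored as little-endian 16-bit integers with a per-channel
#' gain chosen to span the value range, so the write-read round trip is exact
#' to one quantization step.
#'
#' @param record A [bp_record()].
#' @param path Output record path without extension.
#' @return `path`, invisibly.
#' @export
write_record_wfdb <- function(record, path) {
  nsig <- length(record$channels)
  n <- record$length
  base <- basename(path)
  gains <- numeric(nsig)
  offsets <- numeric(nsig)
  dat <- matrix(0L, nrow = nsig, ncol = n)
  for (i in seq_len(nsig)) {
    x <- record$channels[[i]]
    rng <- max(x) - min(x)
    gains[i] <- if (rng > 0) 60000 / rng else 1
    offsets[i] <- min(x)
    dat[i, ] <- as.integer(round((x - offsets[i]) * gains[i]) - 30000)
  }
  hea <- c(
    sprintf("%s %d %g %d", base, nsig, record$fs, n),
    sprintf("%s.dat 16 %.10g(%d)/mV 16 0 %d 0 0 %s",
            base, gains, -30000L - as.integer(round(offsets * gains)),
            dat[, 1], names(record$channels))
  )
  writeLines(hea, paste0(path, ".hea"))
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(dat)), con, size = 2L, endian = "little")
  invisible(path)
}

read_record_wfdb <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop_cuffbp("WFDB header not found: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec_line <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(rec_line[2])
  fs <- as.numeric(rec_line[3])
  n <- as.integer(rec_line[4])
  sig <- lines[2:(1 + nsig)]
  parts <- strsplit(trimws(sig), "\\s+")
  fmt <- vapply(parts, `[[`, "", 2)
  if (any(sub("x.*", "", fmt) != "16")) {
    stop_cuffbp("only WFDB format 16 is supported (got ", paste(fmt, collapse = ", "), ")")
  }
  gain_spec <- vapply(parts, `[[`, "", 3)
  gains <- as.numeric(sub("\\(.*", "", gain_spec))
  gains[is.na(gains) | gains == 0] <- 200 # WFDB default gain
  baselines <- ifelse(grepl("\\(", gain_spec),
                      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_spec)), 0)
  chan_names <- vapply(parts, function(p) paste(p[9:length(p)], collapse = " "), "")
  dat_file <- file.path(dirname(hea_path), vapply(parts, `[[`, "", 1)[1])
  con <- file(dat_file, "rb")
  on.exit(close(con))
  raw <- readBin(con, "integer", n = nsig * n, size = 2L, signed = TRUE,
                 endian = "little")
  dat <- matrix(raw, nrow = nsig)
  channels <- lapply(seq_len(nsig), function(i) (dat[i, ] - baselines[i]) / gains[i])
  names(channels) <- chan_names
  bp_record(channels, fs = fs, source_id = sub("\\.hea$", "", basename(hea_path)))
}

#' Collection protocol specification
#'
#' Defaults reproduce the seven-minute protocol: skip the first minute of the
#' recording, then keep seven one-minute windows separated by 30-s gaps
#' (11 minutes of source signal in total).
#'
#' @param skip_initial Seconds discarded at the start of the record.
#' @param n_windows Number of kept windows.
#' @param window_len Window length in seconds.
#' @param gap_len Gap between consecutive windows in seconds.
#' @return An object of class `bp_collection_spec`.
#' @export
collection_spec <- function(skip_initial = 60, n_windows = 7,
                            window_len = 60, gap_len = 30) {
  check_number(skip_initial, "skip_initial", 0, Inf)
  check_number(n_windows, "n_windows", 1, Inf)
  check_number(window_len, "window_len", 1e-9, Inf)
  check_number(gap_len, "gap_len", 0, Inf)
  structure(list(skip_initial = skip_initial, n_windows = as.integer(n_windows),
                 window_len = window_len, gap_len = gap_len),
            class = "bp_collection_spec")
}

#' Extract and concatenate the collection windows of a record
#'
#' Applies a [collection_spec()] to a record and concatenates the kept
#' windows, so the output always has exactly
#' `n_windows * window_len * fs` samples. Within each kept window, short NA
#' runs (<= `max_na_gap` seconds) are linearly interpolated; a window with a
#' longer NA run raises an error naming the window.
#'
#' @param record A [bp_record()].
#' @param spec A [collection_spec()].
#' @param max_na_gap Longest interpolatable NA run, in seconds.
#' @return A [bp_record()] holding the concatenated windows.
#' @export
extract_collection_windows <- function(record, spec = collection_spec(),
                                       max_na_gap = 0.2) {
  fs <- record$fs
  need <- spec$skip_initial + spec$n_windows * spec$window_len +
    (spec$n_windows - 1) * spec$gap_len
  have <- record$length / fs
  if (have < need) {
    stop_cuffbp(sprintf(
      "record too short for the collection protocol: need %.1f s, have %.1f s",
      need, have))
  }
  wlen <- round(spec$window_len * fs)
  starts <- round((spec$skip_initial +
                     (seq_len(spec$n_windows) - 1) * (spec$window_len + spec$gap_len)) * fs) + 1L
  idx <- unlist(lapply(starts, function(s) seq.int(s, s + wlen - 1L)))
  channels <- lapply(record$channels, function(x) {
    out <- x[idx]
    fill_na_runs(out, max_run = round(max_na_gap * fs), wlen = wlen)
  })
  out <- bp_record(channels, fs = fs, source_id = record$source_id)
  out$window_starts <- starts
  out
}

# Linear interpolation of NA runs no longer than max_run samples; a longer
# run inside any window is an error reporting the window number.
fill_na_runs <- function(x, max_run, wlen) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values & r$lengths > max_run)
  if (length(bad)) {
    w <- (starts[bad[1]] - 1L) %/% wlen + 1L
    stop_cuffbp(sprintf(
      "NA run of %d samples in collection window %d exceeds the interpolatable limit (%d)",
      r$lengths[bad[1]], w, max_run))
  }
  ok <- which(!is.na(x))
  x[-ok] <- stats::approx(ok, x[ok], xout = which(is.na(x)), rule = 2)$y
  x
}

#' Export the four training channels of a record to CSV
#'
#' Writes a CSV with header `ECG, PLETH, ABP Sys, ABP Dias` and one row per
#' sample, at full floating precision.
#'
#' @param record A [bp_record()] containing an ECG channel, `PLETH`,
#'   `ABP Sys` and `ABP Dias`.
#' @param out_path Output file path.
#' @return `out_path`, invisibly.
#' @export
export_training_csv <- function(record, out_path) {
  need <- c("PLETH", "ABP Sys", "ABP Dias")
  missing <- setdiff(need, names(record$channels))
  if (length(missing)) {
    stop_cuffbp("record is missing channel(s): ", paste(missing, collapse = ", "))
  }
  ecg <- record$channels[[ecg_channel(record)]]
  df <- data.frame(
    ECG = ecg,
    PLETH = record$channels[["PLETH"]],
    "ABP Sys" = record$channels[["ABP Sys"]],
    "ABP Dias" = record$channels[["ABP Dias"]],
    check.names = FALSE
  )
  if (nrow(df) == 0) {
    warning("record is empty; writing a header-only CSV", call. = FALSE)
  }
  write.csv(df, out_path, row.names = FALSE)
  invisible(out_path)
}
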