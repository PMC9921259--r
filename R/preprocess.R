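# ECG/PPG conditioning: polynomial baseline-wander removal, Savitzky-Golay
# denoising, and per-record min-max normalization.

#' Remove baseline wander by polynomial detrending
#'
#' Fits a least-squares polynomial of the given degree to the whole signal
#' and subtracts it. A degree-d polynomial over a window of T seconds can
#' only follow oscillations up to roughly d / (2T) Hz, so the pipeline
#' applies this window-wise (degree 6 per 10-s chunk by default), which
#' removes the 0.15-0.2 Hz respiratory wander band almost completely while
#' leaving QRS energy intact.
#'
#' @param signal Numeric vector.
#' @param detrend_order Polynomial degree (>= 0).
#' @return Detrended signal (same length; mean approximately zero).
#' @export
remove_baseline <- function(signal, detrend_order = 6) {
  check_number(detrend_order, "detrend_order", 0, Inf)
  n <- length(signal)
  if (n <= detrend_order + 1) {
    stop_cuffbp(sprintf("signal too short (%d samples) for degree-%d detrending",
                        n, detrend_order))
  }
  if (detrend_order == 0) return(signal - mean(signal))
  t <- seq_len(n)
  fit <- lm.fit(cbind(1, poly(t, degree = detrend_order)), signal)
  as.numeric(fit$residuals)
}

#' Savitzky-Golay denoising
#'
#' Local least-squares polynomial smoothing. The filter reproduces any
#' polynomial of degree at most `sg_polyorder` exactly. Record edges are
#' handled by mirror-padding half a window on each side before filtering, so
#' the output keeps the input length. Defaults (15 samples = 120 ms at
#' 125 Hz, cubic) preserve QRS width while smoothing high-frequency noise.
#'
#' @param signal Numeric vector, at least `sg_window` samples long.
#' @param sg_window Odd window length in samples.
#' @param sg_polyorder Polynomial order (< `sg_window`).
#' @return Smoothed signal of the same length.
#' @export
sg_denoise <- function(signal, sg_window = 15, sg_polyorder = 3) {
  if (sg_window %% 2 != 1 || sg_polyorder >= sg_window || sg_polyorder < 0) {
    stop_cuffbp("need an odd sg_window greater than sg_polyorder")
  }
  n <- length(signal)
  if (n < sg_window) {
    stop_cuffbp(sprintf("signal (%d samples) shorter than sg_window (%d)",
                        n, sg_window))
  }
  half <- (sg_window - 1) / 2
  # mirror padding: reflect without repeating the edge sample
  padded <- c(signal[(half + 1):2], signal, signal[(n - 1):(n - half)])
  coefs <- signal::sgolay(p = sg_polyorder, n = sg_window)
  smoother <- coefs[half + 1, ] # central row smooths; S-G is a convolution
  out <- stats::filter(padded, smoother, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Min-max normalization to the unit interval
#'
#' Maps a signal affinely so its minimum becomes 0 and its maximum 1,
#' matching the per-record value-range normalization applied before peak
#' detection.
#'
#' @param signal Non-empty numeric vector with a non-zero value range.
#' @return Normalized signal.
#' @export
normalize_minmax <- function(signal) {
  if (!length(signal)) stop_cuffbp("cannot normalize an empty signal")
  lo <- min(signal)
  hi <- max(signal)
  if (hi - lo <= 0) {
    stop_cuffbp("flat channel: signal has zero value range, cannot normalize")
  }
  (signal - lo) / (hi - lo)
}

#' Preprocessing configuration
#'
#' @param detrend_order Polynomial degree for ECG baseline removal, applied
#'   per `detrend_window`-second chunk.
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @param detrend_window Chunk length (s) for window-wise detrending.
#' @return An object of class `bp_preprocess_config`.
#' @export
preprocess_config <- function(detrend_order = 6, sg_window = 15,
                              sg_polyorder = 3, detrend_window = 10) {
  structure(list(detrend_order = detrend_order, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, detrend_window = detrend_window),
            class = "bp_preprocess_config")
}

#' Preprocess the ECG and PPG channels of a record
#'
#' ECG: window-wise polynomial detrending, Savitzky-Golay denoising, min-max
#' normalization. PPG: Savitzky-Golay denoising and normalization only (no
#' detrending). Returns the record with channels `ECG_norm` and `PLETH_norm`
#' added.
#'
#' @param record A [bp_record()].
#' @param config A [preprocess_config()].
#' @return The record with normalized channels attached.
#' @export
preprocess_record <- function(record, config = preprocess_config()) {
  ecg <- record$channels[[ecg_channel(record)]]
  wlen <- round(config$detrend_window * record$fs)
  ecg_dt <- detrend_windowwise(ecg, config$detrend_order, wlen)
  ecg_sm <- sg_denoise(ecg_dt, config$sg_window, config$sg_polyorder)
  ppg_sm <- sg_denoise(record$channels[["PLETH"]], config$sg_window,
                       config$sg_polyorder)
  record$channels[["ECG_norm"]] <- normalize_minmax(ecg_sm)
  record$channels[["PLETH_norm"]] <- normalize_minmax(ppg_sm)
  record$length <- length(record$channels[[1]])
  record
}

detrend_windowwise <- function(x, order, wlen) {
  n <- length(x)
  if (n <= wlen) return(remove_baseline(x, order))
  starts <- seq.int(1L, n, by = wlen)
  out <- numeric(n)
  for (s in starts) {
    e <- min(s + wlen - 1L, n)
    if (e - s + 1L <= order + 1L) { # tiny tail: merge into previous chunk
      out[s:e] <- x[s:e] - mean(x[s:e])
    } else {
      out[s:e] <- remove_baseline(x[s:e], order)
    }
  }
  out
}
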