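#' Estimate time-of-arrival differences by cross-correlation
#'
#' For one detected call, cross-correlates each non-reference channel with
#' the reference channel inside the detection window and reports the
#' time-of-arrival difference (TOAD) per microphone. The sign convention is
#' fixed throughout the package as
#' \deqn{toad_i = t_{mic_i} - t_{reference},}
#' i.e. a positive TOAD means the call arrived at microphone i later than at
#' the reference microphone. The correlation peak is searched only over
#' physically possible lags (|lag| <= baseline/c plus one sample) and
#' refined to sub-sample precision by parabolic interpolation of the
#' three-point peak neighbourhood.
#'
#' @param rec a [bat_recording()] with one channel per microphone.
#' @param det one row of the [detect_calls()] output (or a list with
#'   `window_start`/`window_end`).
#' @param array a [mic_array()].
#' @param band pass band in Hz used before correlation (default 15-120 kHz).
#' @param c_sound speed of sound in m/s (default 343).
#' @param min_peak normalised correlation below which a channel's TOAD is
#'   flagged invalid (default 0.2).
#'
#' @return An object of class `toad_set`: list with `toads` (7 values in
#'   seconds, `NA` where invalid), `peak_correlations` (7 normalised peak
#'   heights), `mic_index` (the microphone index of each entry),
#'   `detection_time` (arrival time at the reference microphone, seconds
#'   into the recording) and `n_valid`.
#' @export
estimate_toads <- function(rec, det, array, band = c(15e3, 120e3),
                           c_sound = 343, min_peak = 0.2) {
  stopifnot(inherits(rec, "bat_recording"), inherits(array, "mic_array"))
  fs <- rec$sample_rate
  s0 <- max(1L, as.integer(round(det$window_start * fs)) + 1L)
  s1 <- min(nrow(rec$samples), as.integer(round(det$window_end * fs)))
  if (s1 <= s0) stop("invalid detection window")
  max_baseline <- array$aperture
  max_lag_s <- max_baseline / c_sound
  if ((s1 - s0 + 1) / fs < 2 * max_lag_s)
    stop("detection window shorter than twice the maximum possible TOAD")
  win <- bandpass_matrix(rec$samples[s0:s1, , drop = FALSE], fs, band)
  ref_i <- array$reference_index
  ref <- win[, ref_i]
  others <- setdiff(seq_len(nrow(array$mic_positions)), ref_i)
  toads <- rep(NA_real_, length(others))
  peaks <- numeric(length(others))
  e_ref <- sum(ref^2)
  for (j in seq_along(others)) {
    ch <- win[, others[j]]
    e_ch <- sum(ch^2)
    if (e_ch <= 0 || e_ref <= 0) next
    baseline <- sqrt(sum((array$mic_positions[others[j], ] -
                          array$mic_positions[ref_i, ])^2))
    max_lag <- floor(baseline / c_sound * fs) + 1L
    cc <- xcorr_fft(ch, ref, max_lag)
    pk <- which.max(cc$value)
    peak_norm <- cc$value[pk] / sqrt(e_ch * e_ref)
    peaks[j] <- peak_norm
    if (peak_norm < min_peak) next
    lag <- cc$lag[pk]
    # parabolic sub-sample refinement (skip at the search boundary)
    if (pk > 1L && pk < length(cc$value)) {
      cm <- cc$value[pk - 1L]; c0 <- cc$value[pk]; cp <- cc$value[pk + 1L]
      den <- cm - 2 * c0 + cp
      if (den < 0) lag <- lag + 0.5 * (cm - cp) / den
    }
    toads[j] <- lag / fs
  }
  # arrival time at the reference microphone: envelope peak within window
  t_ref <- det$window_start + (which.max(abs(ref)) - 1L) / fs
  structure(
    list(toads = toads, peak_correlations = peaks, mic_index = others,
         detection_time = t_ref, n_valid = sum(!is.na(toads))),
    class = "toad_set"
  )
}

#' @export
print.toad_set <- function(x, ...) {
  cat(sprintf("TOAD set at t = %.4f s: %d/%d valid channels\n",
              x$detection_time, x$n_valid, length(x$toads)))
  cat("  toads (us):",
      paste(ifelse(is.na(x$toads), "NA",
                   sprintf("%.1f", x$toads * 1e6)), collapse = " "), "\n")
  invisible(x)
}

# Cross-correlation of a against b over lags -max_lag..max_lag via
# zero-padded FFT; cc[k] = sum_n a[n] b[n-k], so the peak lag is positive
# when a is a delayed copy of b.
xcorr_fft <- function(a, b, max_lag) {
  n <- length(a)
  max_lag <- min(max_lag, n - 1L)
  nfft <- 2^ceiling(log2(2L * n))
  fa <- stats::fft(c(a, rep(0, nfft - n)))
  fb <- stats::fft(c(b, rep(0, nfft - n)))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / nfft
  lags <- -max_lag:max_lag
  # circular indexing: lag k lives at index k+1 (mod nfft)
  vals <- cc[(lags %% nfft) + 1L]
  list(lag = lags, value = vals)
}
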