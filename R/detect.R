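#' Detect candidate echolocation calls in a multichannel recording
#'
#' Energy detector: each channel is band-pass filtered, short-time energy is
#' computed on 1 ms frames, and a frame is "hot" when its energy on any
#' channel exceeds `threshold` times that channel's rolling-median noise
#' floor (100 ms window). Runs of hot frames become detections; detections
#' closer than `holdoff` are merged, so a call and its immediate neighbours
#' (or echoes) yield a single window.
#'
#' @param rec a [bat_recording()].
#' @param band numeric length-2 pass band in Hz, inside (0, sample_rate/2).
#'   Default 15-120 kHz covers the FM sweeps of European vespertilionids.
#' @param threshold energy ratio over the rolling noise floor that triggers
#'   a detection (default 8).
#' @param holdoff minimum separation in seconds below which detections are
#'   merged (default 0.02).
#' @param frame analysis frame length in seconds (default 0.001).
#' @param floor_window rolling-median window for the noise floor in seconds
#'   (default 0.1).
#' @param pad seconds added on both sides of each hot run so the full call
#'   and its inter-channel arrival spread fall inside the window (default
#'   0.008; at 343 m/s this covers the largest possible arrival spread of a
#'   2 m aperture array with room to spare).
#'
#' @return A data frame of class `call_detections` with columns
#'   `window_start`, `window_end` (seconds into the recording),
#'   `trigger_channel` (channel with the largest floor-relative energy) and
#'   `peak_amplitude` (band-limited peak amplitude on the trigger channel).
#'   Windows are non-overlapping and sorted by time.
#' @export
detect_calls <- function(rec, band = c(15e3, 120e3), threshold = 8,
                         holdoff = 0.02, frame = 0.001, floor_window = 0.1,
                         pad = 0.008) {
  stopifnot(inherits(rec, "bat_recording"))
  fs <- rec$sample_rate
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= fs / 2)
    stop("band must be an increasing pair inside (0, sample_rate/2)")
  n <- nrow(rec$samples)
  empty <- data.frame(window_start = numeric(0), window_end = numeric(0),
                      trigger_channel = integer(0),
                      peak_amplitude = numeric(0))
  class(empty) <- c("call_detections", "data.frame")
  if (n == 0L) return(empty)

  filt <- bandpass_matrix(rec$samples, fs, band)
  flen <- max(1L, as.integer(round(frame * fs)))
  nfr <- n %/% flen
  if (nfr < 2L) return(empty)
  nch <- ncol(filt)
  # per-frame energy, channels in columns
  e <- matrix(0, nfr, nch)
  idx <- seq_len(nfr * flen)
  for (ch in seq_len(nch)) {
    x2 <- filt[idx, ch]^2
    e[, ch] <- colSums(matrix(x2, nrow = flen))
  }
  k <- as.integer(round(floor_window / frame))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (nfr %% 2L == 1L) nfr else nfr - 1L)
  ratio <- matrix(0, nfr, nch)
  for (ch in seq_len(nch)) {
    fl <- stats::runmed(e[, ch], k, endrule = "median")
    fl <- pmax(fl, .Machine$double.eps)
    ratio[, ch] <- e[, ch] / fl
  }
  hot <- apply(ratio, 1, max) > threshold
  if (!any(hot)) return(empty)

  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by less than the holdoff
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    gap_frames <- holdoff / frame
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] <= gap_frames)
        merged[nrow(merged), 2] <- runs[i, 2]
      else
        merged <- rbind(merged, runs[i, ])
    }
  }
  ws <- pmax(0, (merged[, 1] - 1) * frame - pad)
  we <- pmin(n / fs, merged[, 2] * frame + pad)
  # clip overlaps introduced by padding
  if (length(ws) > 1L)
    for (i in 2:length(ws))
      if (ws[i] < we[i - 1]) {
        mid <- (merged[i, 1] - 1 + merged[i - 1, 2]) / 2 * frame
        ws[i] <- mid; we[i - 1] <- mid
      }
  trig <- integer(length(ws)); peak <- numeric(length(ws))
  for (i in seq_along(ws)) {
    fr <- merged[i, 1]:merged[i, 2]
    trig[i] <- which.max(apply(ratio[fr, , drop = FALSE], 2, max))
    s0 <- max(1L, as.integer(ws[i] * fs) + 1L)
    s1 <- min(n, as.integer(we[i] * fs))
    peak[i] <- max(abs(filt[s0:s1, trig[i]]))
  }
  out <- data.frame(window_start = ws, window_end = we,
                    trigger_channel = trig, peak_amplitude = peak)
  class(out) <- c("call_detections", "data.frame")
  out
}

# zero-phase Butterworth band-pass applied column-wise
bandpass_matrix <- function(x, fs, band, order = 4L) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}
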