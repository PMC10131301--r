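#' Multichannel recordings and 16-bit PCM WAV input/output
#'
#' A `bat_recording` holds a multichannel ultrasonic recording: a numeric
#' N x n_channels matrix of unit-scaled amplitudes (column k is microphone
#' channel k), the sampling rate in Hz (field default 300 kHz) and the start
#' time of the recording in seconds.
#'
#' @param samples numeric matrix, one column per channel, amplitudes in
#'   [-1, 1].
#' @param sample_rate sampling rate in Hz, > 0.
#' @param start_time recording start time in seconds (default 0).
#' @return An object of class `bat_recording`.
#' @export
bat_recording <- function(samples, sample_rate, start_time = 0) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = "bat_recording"
  )
}

#' @export
print.bat_recording <- function(x, ...) {
  cat(sprintf("Recording: %d channels, %.3f s at %g kHz\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate,
              x$sample_rate / 1000))
  invisible(x)
}

# Minimal RIFF/WAVE 16-bit PCM codec. No audio package ships with the
# package's dependency set, and the format is simple enough that the two
# functions below cover exactly what the toolchain needs: interleaved 16-bit
# little-endian PCM with an arbitrary number of channels and sample rate.

#' Read a multichannel 16-bit PCM WAV file
#'
#' @param path file path.
#' @return A [bat_recording()] with amplitudes scaled to [-1, 1) by 1/32768.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sample_rate <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size / 2, 2, endian = "little",
                     signed = FALSE)
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      n_channels <- fmt[2]
      sample_rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (bits != 16L) stop("only 16-bit WAV is supported")
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", size / 2, 2, endian = "little",
                      signed = TRUE)
      break
    } else {
      seek(con, size, origin = "current")
    }
  }
  if (is.null(data) || is.null(sample_rate))
    stop("malformed WAV file (missing fmt or data chunk): ", path)
  mat <- matrix(data / 32768, ncol = n_channels, byrow = TRUE)
  bat_recording(mat, sample_rate)
}

#' Write a multichannel 16-bit PCM WAV file
#'
#' Amplitudes are clipped to [-1, 1) and quantised to 16 bits.
#'
#' @param rec a [bat_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "bat_recording"))
  x <- t(rec$samples)                       # interleave channels
  q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_channels <- ncol(rec$samples)
  byte_rate <- rec$sample_rate * n_channels * 2
  data_size <- length(q) * 2
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, n_channels), con, 2, endian = "little")
  writeBin(as.integer(rec$sample_rate), con, 4, endian = "little")
  writeBin(as.integer(byte_rate), con, 4, endian = "little")
  writeBin(c(as.integer(n_channels * 2), 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}
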