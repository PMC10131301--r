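#' Linear-period FM downsweep call model
#'
#' Evaluates a Hann-windowed linear-period frequency-modulated downsweep
#' (default 100 kHz down to 45 kHz over 5 ms, a pipistrelle-like search
#' call) at arbitrary times since call onset. Linear-period FM means the
#' instantaneous period grows linearly over the call, giving the hyperbolic
#' frequency sweep typical of vespertilionid calls.
#'
#' @param tau times since call onset in seconds (values outside [0,
#'   duration] give 0).
#' @param f_start,f_end start/end frequencies in Hz (default 100 kHz, 45
#'   kHz).
#' @param duration call duration in seconds (default 0.005).
#' @return Amplitudes in [-1, 1].
#' @export
fm_call <- function(tau, f_start = 100e3, f_end = 45e3, duration = 0.005) {
  t0 <- 1 / f_start
  k <- (1 / f_end - t0) / duration          # period slope (s per s)
  inside <- tau >= 0 & tau <= duration
  out <- numeric(length(tau))
  tt <- tau[inside]
  phase <- if (abs(k) < 1e-12) 2 * pi * f_start * tt
           else 2 * pi / k * log1p(k * tt / t0)
  window <- 0.5 * (1 - cos(2 * pi * tt / duration))
  out[inside] <- sin(phase) * window
  out
}

#' Synthesise a multichannel recording of a flight path
#'
#' The forward model the localiser inverts: each call on the path is an FM
#' downsweep placed on every microphone channel with its exact propagation
#' delay (distance/c, including the fractional-sample part), spherical
#' spreading amplitude decay (1/r, unit source level referenced to 1 m),
#' and additive white Gaussian noise. A channel receives nothing for a
#' call whose source-to-microphone segment passes through a trunk (hard
#' occlusion - the acoustic-shadow mechanism). Microphone positions are
#' the array geometry placed in the scene by the array pose.
#'
#' @param path a [generate_flight_path()] result (scene frame).
#' @param array a [mic_array()].
#' @param scene a [bat_scene()].
#' @param sample_rate sampling rate in Hz (default 300 kHz).
#' @param c_sound speed of sound in m/s (default 343).
#' @param snr_db per-call peak signal-to-noise ratio in dB for a call
#'   received at the 10 m reference range (default 30).
#' @param f_start,f_end,call_duration call model parameters, see
#'   [fm_call()].
#' @param seed seed (default the scene's).
#' @return List with `recording` (a [bat_recording()]) and `truth` (data
#'   frame: `call_id`, `time` emission time, `x`, `y`, `z` scene frame,
#'   `n_visible` channels reached, `occluded` semicolon-separated occluded
#'   channel indices).
#' @export
synthesise_recording <- function(path, array, scene, sample_rate = 300e3,
                                 c_sound = 343, snr_db = 30,
                                 f_start = 100e3, f_end = 45e3,
                                 call_duration = 0.005,
                                 seed = scene$seed) {
  stopifnot(inherits(array, "mic_array"), inherits(scene, "bat_scene"))
  set.seed(seed)
  mics <- apply_transform(scene$array_pose, array$mic_positions)
  n_mic <- nrow(mics)
  max_delay <- max(apply(as.matrix(path[, c("x", "y", "z")]), 1, function(p)
    max(sqrt(rowSums(sweep(mics, 2, p)^2))))) / c_sound
  total <- max(path$time) + max_delay + call_duration + 0.05
  n <- ceiling(total * sample_rate)
  noise_sd <- (1 / 10) / 10^(snr_db / 20)   # unit source level at 10 m ref
  samples <- matrix(stats::rnorm(n * n_mic, sd = noise_sd), n, n_mic)
  n_call_samp <- ceiling(call_duration * sample_rate) + 2L
  truth <- data.frame(call_id = seq_len(nrow(path)), time = path$time,
                      x = path$x, y = path$y, z = path$z,
                      n_visible = 0L, occluded = "",
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(path))) {
    src <- c(path$x[i], path$y[i], path$z[i])
    occ <- integer(0)
    for (m in seq_len(n_mic)) {
      if (segment_occluded(src, mics[m, ], scene$trunks)) {
        occ <- c(occ, m)
        next
      }
      d <- sqrt(sum((src - mics[m, ])^2))
      t_arr <- path$time[i] + d / c_sound
      i0 <- floor(t_arr * sample_rate) + 1L
      idx <- i0:(i0 + n_call_samp)
      idx <- idx[idx >= 1L & idx <= n]
      tau <- (idx - 1) / sample_rate - t_arr
      samples[idx, m] <- samples[idx, m] +
        fm_call(tau, f_start, f_end, call_duration) / max(d, 0.1)
    }
    truth$n_visible[i] <- n_mic - length(occ)
    truth$occluded[i] <- paste(occ, collapse = ";")
  }
  list(recording = bat_recording(samples, sample_rate), truth = truth)
}
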