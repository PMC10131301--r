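# shared fixture builders (all programmatic, seeded by the caller)

# random unit vector in the upper hemisphere at range r
random_hemisphere_point <- function(r) {
  th <- stats::runif(1, 0, 2 * pi)
  ph <- stats::runif(1, 0, pi / 2)
  r * c(cos(th) * cos(ph), sin(th) * cos(ph), sin(ph))
}

# delay a signal by a (possibly fractional) number of samples, band-limited
delay_samples <- function(x, d) {
  n <- length(x)
  X <- stats::fft(x)
  k <- c(0:(n %/% 2), -(((n + 1) %/% 2 - 1):1))
  Re(stats::fft(X * exp(-2i * pi * k * d / n), inverse = TRUE)) / n
}

# 8-channel recording: reference channel carries a chirp, every other
# channel the same chirp delayed by `shifts` samples; white noise at
# `noise_sd` everywhere
make_shift_recording <- function(array, shifts, fs = 300e3, n = 6000,
                                 noise_sd = 0.005, onset = 0.005) {
  tau <- (0:(n - 1)) / fs - onset
  base <- fm_call(tau)
  m <- matrix(stats::rnorm(n * 8, 0, noise_sd), n, 8)
  ref_i <- array$reference_index
  m[, ref_i] <- m[, ref_i] + base
  others <- setdiff(1:8, ref_i)
  for (j in seq_along(others))
    m[, others[j]] <- m[, others[j]] + delay_samples(base, shifts[j])
  bat_recording(m, fs)
}

full_window <- function(rec) {
  list(window_start = 0, window_end = nrow(rec$samples) / rec$sample_rate)
}

# random proper rotation matrix (QR of a Gaussian matrix, det-corrected)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

# toy position table with prescribed ranges and error pairs
toy_positions <- function(ranges, radial, tangential) {
  n <- length(ranges)
  dir <- matrix(rep(c(1, 1, 1) / sqrt(3), n), n, 3, byrow = TRUE)
  bat_positions(data.frame(
    time = seq_len(n), x = dir[, 1] * ranges, y = dir[, 2] * ranges,
    z = dir[, 3] * ranges, radial_error = radial,
    tangential_error = tangential))
}
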