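#' Theoretical TOADs for a source position
#'
#' Under isotropic spherical sound spreading, the time-of-arrival
#' difference at microphone i relative to the reference microphone for a
#' source at `xyz` is
#' \deqn{toad_i = (\|xyz - mic_i\| - \|xyz - mic_{ref}\|)/c.}
#'
#' @param xyz numeric length-3 source position in metres (array frame).
#' @param array a [mic_array()].
#' @param c_sound speed of sound in m/s (> 0).
#' @return Numeric vector of 7 TOADs in seconds, ordered as the
#'   non-reference microphones.
#' @seealso [speed_of_sound()] for a temperature model.
#' @export
theoretical_toads <- function(xyz, array, c_sound = 343) {
  stopifnot(inherits(array, "mic_array"), c_sound > 0)
  xyz <- as.numeric(xyz)
  d <- sqrt(rowSums(sweep(array$mic_positions, 2, xyz)^2))
  ref_i <- array$reference_index
  unname((d[-ref_i] - d[ref_i]) / c_sound)
}

#' Speed of sound in air as a function of temperature
#'
#' @param temperature_c air temperature in degrees Celsius.
#' @return Speed of sound in m/s, \eqn{331.3\sqrt{1 + T/273.15}}.
#' @export
speed_of_sound <- function(temperature_c) {
  331.3 * sqrt(1 + temperature_c / 273.15)
}

#' Localise a sound source from a TOAD set by multilateration
#'
#' Finds the source position whose theoretical TOADs best match the
#' observed ones in the least-squares sense, using damped iterative least
#' squares (Levenberg-Marquardt) started from a coarse deterministic grid
#' over the monitored hemisphere; the start with the smallest initial
#' residual norm seeds the refinement and the best-residual solution wins.
#' With the eight-microphone overdetermined array the fit residuals also
#' yield localisation error estimates (see Details).
#'
#' @details With more than four valid microphones the array is
#'   overdetermined and the error of the fitted position can be assessed by
#'   comparing observed and theoretical TOADs. The package propagates the
#'   residual variance through the linearised model: with Jacobian J of the
#'   theoretical TOADs with respect to position and residual variance
#'   s^2 = RSS/(n-3), the position covariance is C = s^2 (J'J)^-1. The
#'   \emph{radial error} is the 1-sigma uncertainty along the line from the
#'   array centre to the position (sqrt(r' C r) for the radial unit vector
#'   r); the \emph{tangential error} is the 1-sigma uncertainty in the
#'   plane perpendicular to that line (sqrt of the trace of C projected on
#'   the plane); the \emph{max TOAD distance error} is the largest
#'   per-microphone TOAD misfit expressed as a distance,
#'   c * max|observed - theoretical|. Exactly four microphones give no
#'   redundancy: the position is computed but flagged unassessable.
#'
#' @param toads a `toad_set` from [estimate_toads()], or a bare numeric
#'   vector of 7 TOADs in seconds (NA = invalid channel).
#' @param array a [mic_array()].
#' @param c_sound speed of sound in m/s.
#' @param residual_cap RMS TOAD residual in seconds above which the
#'   position is flagged invalid (default 3e-5 s, i.e. about 1 cm of path
#'   mismatch per microphone).
#' @param grid_radii,grid_directions multi-start grid: radii in metres and
#'   number of directions over the upper hemisphere-ish shell (26 =
#'   the non-zero sign patterns of a 3 x 3 x 3 lattice).
#' @param n_refine number of best grid starts refined by the damped
#'   least-squares iteration (default 5).
#'
#' @return A one-row data frame of class `bat_positions` with columns
#'   `time`, `x`, `y`, `z`, `radial_error`, `tangential_error`,
#'   `max_toad_error`, `residual_rms`, `n_mics`, `valid`, `guild`.
#'   Error columns are `NA` when the solution is unassessable (4
#'   microphones, no redundancy) or degenerate.
#' @export
localise <- function(toads, array, c_sound = 343, residual_cap = 3e-5,
                     grid_radii = c(2, 5, 10, 20, 40),
                     grid_directions = 26L, n_refine = 5L) {
  stopifnot(inherits(array, "mic_array"), c_sound > 0)
  if (inherits(toads, "toad_set")) {
    tv <- toads$toads
    t_det <- toads$detection_time
  } else {
    tv <- as.numeric(toads)
    t_det <- NA_real_
  }
  ref_i <- array$reference_index
  others <- setdiff(seq_len(nrow(array$mic_positions)), ref_i)
  if (length(tv) != length(others))
    stop("expected one TOAD per non-reference microphone")
  ok <- !is.na(tv)
  n_mics <- sum(ok) + 1L
  if (n_mics < 4L)
    stop("at least 4 valid microphones (including the reference) are ",
         "needed for 3D localisation; got ", n_mics)
  mics <- array$mic_positions
  obs <- tv[ok]
  mid <- others[ok]

  resid_fn <- function(p) {
    d <- sqrt(rowSums(sweep(mics, 2, p)^2))
    (d[mid] - d[ref_i]) / c_sound - obs
  }
  jac_fn <- function(p) {
    diffs <- -sweep(mics, 2, p)              # p - mic, per row
    d <- sqrt(rowSums(diffs^2))
    u <- diffs / pmax(d, 1e-12)              # unit vectors mic -> p
    (u[mid, , drop = FALSE] -
       matrix(u[ref_i, ], length(mid), 3, byrow = TRUE)) / c_sound
  }

  starts <- multistart_grid(array, grid_radii, grid_directions)
  ssq <- apply(starts, 1, function(p) sum(resid_fn(p)^2))
  ord <- order(ssq)[seq_len(min(n_refine, nrow(starts)))]
  best <- NULL
  for (i in ord) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], fn = resid_fn, jac = jac_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop("localisation failed to converge from any start")
  xyz <- as.numeric(best$par)
  res <- resid_fn(xyz)
  n_toads <- length(obs)
  residual_rms <- sqrt(mean(res^2))

  radial <- tangential <- max_toad <- NA_real_
  degenerate <- FALSE
  if (n_toads >= 4L) {                       # >= 5 mics: redundancy
    J <- jac_fn(xyz)
    s2 <- sum(res^2) / (n_toads - 3L)
    JtJ <- crossprod(J)
    Cpos <- try(solve(JtJ) * s2, silent = TRUE)
    if (inherits(Cpos, "try-error") || any(!is.finite(Cpos))) {
      degenerate <- TRUE
    } else {
      r_hat <- xyz - array$centre
      nr <- sqrt(sum(r_hat^2))
      if (nr < 1e-9) {
        degenerate <- TRUE
      } else {
        r_hat <- r_hat / nr
        radial <- sqrt(max(0, drop(t(r_hat) %*% Cpos %*% r_hat)))
        tangential <- sqrt(max(0, sum(diag(Cpos)) - radial^2))
        max_toad <- c_sound * max(abs(res))
      }
    }
  }
  valid <- is.finite(residual_rms) && residual_rms <= residual_cap &&
    !degenerate
  t_emit <- if (is.finite(t_det))
    t_det - sqrt(sum((xyz - mics[ref_i, ])^2)) / c_sound else NA_real_
  out <- data.frame(
    time = t_emit, x = xyz[1], y = xyz[2], z = xyz[3],
    radial_error = radial, tangential_error = tangential,
    max_toad_error = max_toad, residual_rms = residual_rms,
    n_mics = n_mics, valid = valid, guild = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bat_positions", "data.frame")
  attr(out, "frame") <- "array"
  out
}

# deterministic multi-start grid: 26 lattice directions x radii, plus the
# array centre's near field
multistart_grid <- function(array, radii, n_dir = 26L) {
  g <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  g <- as.matrix(g[rowSums(abs(g)) > 0, ])
  g <- g / sqrt(rowSums(g^2))
  if (n_dir < nrow(g)) g <- g[seq_len(n_dir), , drop = FALSE]
  starts <- do.call(rbind, lapply(radii, function(r)
    sweep(g * r, 2, array$centre, "+")))
  starts
}

#' Assess localisation errors for a fitted position
#'
#' Standalone access to the error decomposition documented in
#' [localise()]: linearised error propagation of the TOAD residuals at the
#' fitted position, split into radial and tangential components, plus the
#' maximum TOAD misfit expressed as a distance.
#'
#' @param pos one-row `bat_positions` (or numeric xyz).
#' @param toads observed TOADs (a `toad_set` or 7-vector, NA = invalid).
#' @param array a [mic_array()].
#' @param c_sound speed of sound in m/s.
#' @return A list with `radial_error`, `tangential_error`,
#'   `max_toad_error` (metres). Positions fitted with only four
#'   microphones have no redundancy: all three are `NA`.
#' @export
assess_errors <- function(pos, toads, array, c_sound = 343) {
  xyz <- if (is.data.frame(pos)) as.numeric(pos[1, c("x", "y", "z")])
         else as.numeric(pos)
  tv <- if (inherits(toads, "toad_set")) toads$toads else as.numeric(toads)
  ok <- !is.na(tv)
  if (sum(ok) < 4L)
    return(list(radial_error = NA_real_, tangential_error = NA_real_,
                max_toad_error = NA_real_))
  th <- theoretical_toads(xyz, array, c_sound)
  res <- tv[ok] - th[ok]
  mics <- array$mic_positions
  ref_i <- array$reference_index
  others <- setdiff(seq_len(nrow(mics)), ref_i)[ok]
  diffs <- -sweep(mics, 2, xyz)              # xyz - mic, per row
  d <- sqrt(rowSums(diffs^2))
  u <- diffs / pmax(d, 1e-12)
  J <- (u[others, , drop = FALSE] -
          matrix(u[ref_i, ], length(others), 3, byrow = TRUE)) / c_sound
  s2 <- sum(res^2) / (length(res) - 3L)
  Cpos <- try(solve(crossprod(J)) * s2, silent = TRUE)
  if (inherits(Cpos, "try-error") || any(!is.finite(Cpos)))
    return(list(radial_error = NA_real_, tangential_error = NA_real_,
                max_toad_error = NA_real_))
  r_hat <- xyz - array$centre
  r_hat <- r_hat / sqrt(sum(r_hat^2))
  radial <- sqrt(max(0, drop(t(r_hat) %*% Cpos %*% r_hat)))
  list(
    radial_error = radial,
    tangential_error = sqrt(max(0, sum(diag(Cpos)) - radial^2)),
    max_toad_error = c_sound * max(abs(res))
  )
}
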