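#' Generate a ground-truth flight path
#'
#' Produces a smooth flight path of the requested kind sampled at call
#' emission times (one position per call). Kinds:
#' \describe{
#'   \item{`"circle"`}{stereotyped loop around a named trunk at a set
#'     standoff from the trunk axis, with a small radial jitter - the
#'     circling-around-trees pattern seen in cluttered habitat.}
#'   \item{`"corridor"`}{back-and-forth flight along a named straight
#'     corridor with a gentle lateral weave that stays inside the corridor
#'     polygon.}
#'   \item{`"random-walk"`}{smoothed random heading at constant speed
#'     inside the scene extent.}
#' }
#' Flight speeds are constrained to the plausible 1-15 m/s band.
#'
#' @param kind one of `"circle"`, `"corridor"`, `"random-walk"`.
#' @param scene a [bat_scene()].
#' @param duration path duration in seconds.
#' @param call_rate calls per second (default 8, a cruising pipistrelle).
#' @param speed flight speed in m/s (default 5, must lie in [1, 15]).
#' @param height mean flight height in metres (default 4).
#' @param standoff circle kind: distance from the trunk axis in metres
#'   (default 2).
#' @param trunk circle kind: row index of the circled trunk (default 1).
#' @param corridor corridor kind: name or index of the scene corridor.
#' @param jitter radial jitter s.d. in metres for the circle kind
#'   (default 0.05).
#' @param seed seed (default the scene's).
#' @return A data frame of class `true_path` with columns `time`, `x`,
#'   `y`, `z` (scene frame), and attributes `kind` and `call_interval`.
#' @export
generate_flight_path <- function(kind = c("circle", "corridor",
                                          "random-walk"),
                                 scene, duration = 10, call_rate = 8,
                                 speed = 5, height = 4, standoff = 2,
                                 trunk = 1L, corridor = 1L, jitter = 0.05,
                                 seed = scene$seed) {
  kind <- match.arg(kind)
  stopifnot(call_rate > 0, duration > 0)
  if (speed < 1 || speed > 15)
    stop("speed must lie within the plausible 1-15 m/s flight band")
  set.seed(seed)
  times <- (seq_len(floor(duration * call_rate)) - 1) / call_rate
  n <- length(times)
  if (kind == "circle") {
    if (nrow(scene$trunks) < trunk) stop("scene has no trunk ", trunk)
    tr <- scene$trunks[trunk, ]
    omega <- speed / standoff
    th <- stats::runif(1, 0, 2 * pi) + omega * times
    r <- standoff + stats::rnorm(n, 0, jitter)
    xyz <- cbind(tr$x + r * cos(th), tr$y + r * sin(th),
                 height + 0.3 * sin(2 * pi * times / 7))
  } else if (kind == "corridor") {
    if (is.null(scene$corridors)) stop("scene has no corridors")
    co <- scene$corridors[[corridor]]
    if (is.null(co)) stop("unknown corridor: ", corridor)
    s <- co$start; e <- co$end
    L <- sqrt(sum((e - s)^2))
    d <- (e - s) / L
    nvec <- c(-d[2], d[1])
    # triangle-wave progress along the corridor (fly out, turn, fly back)
    prog <- (speed * times) %% (2 * L)
    along <- ifelse(prog <= L, prog, 2 * L - prog)
    lateral <- 0.3 * co$width / 2 * sin(2 * pi * times / 5)
    xyz <- cbind(s[1] + along * d[1] + lateral * nvec[1],
                 s[2] + along * d[2] + lateral * nvec[2],
                 height + 0.4 * sin(2 * pi * times / 6))
  } else {
    dt <- 1 / call_rate
    heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                        stats::rnorm(n - 1, 0, 0.15)))
    climb <- 0.2 * sin(2 * pi * times / 8)
    ext <- scene$extent
    x <- numeric(n); y <- numeric(n)
    x[1] <- mean(ext[1:2]); y[1] <- mean(ext[3:4])
    for (i in 2:n) {
      x[i] <- x[i - 1] + speed * dt * cos(heading[i])
      y[i] <- y[i - 1] + speed * dt * sin(heading[i])
      # soft reflection at the extent boundary
      if (x[i] < ext[1] || x[i] > ext[2] ||
          y[i] < ext[3] || y[i] > ext[4]) {
        heading[i:n] <- heading[i:n] + pi / 2
        x[i] <- min(max(x[i], ext[1]), ext[2])
        y[i] <- min(max(y[i], ext[3]), ext[4])
      }
    }
    xyz <- cbind(x, y, height + climb)
  }
  out <- data.frame(time = times, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  class(out) <- c("true_path", "data.frame")
  attr(out, "kind") <- kind
  attr(out, "call_interval") <- 1 / call_rate
  out
}
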