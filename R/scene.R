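#' Synthetic scenes
#'
#' A `bat_scene` is the ground-truth description the simulator works from:
#' vertical trunk cylinders, Gaussian foliage blobs, a ground plane at
#' z = 0, a lamppost, the rigid pose placing the microphone array in the
#' scene, optional corridor definitions, and a seed making everything
#' reproducible.
#'
#' @param trunks data frame with columns `x`, `y`, `radius`, `height` and
#'   optionally `base_z` (default 0): vertical cylinders in metres.
#' @param foliage data frame with columns `x`, `y`, `z`, `sigma`,
#'   `n_points`: isotropic Gaussian point blobs.
#' @param lamppost list with `base` (length-3, metres) and `height`
#'   (metres, default 4).
#' @param array_pose a [rigid_transform()] mapping array-frame coordinates
#'   into the scene frame.
#' @param corridors optional named list; each element a list with `start`,
#'   `end` (length-2 XY points) and `width` (metres) describing a straight
#'   corridor.
#' @param extent ground extent `c(xmin, xmax, ymin, ymax)` for ground
#'   returns.
#' @param seed integer seed.
#' @return An object of class `bat_scene`.
#' @export
bat_scene <- function(trunks = NULL, foliage = NULL,
                      lamppost = list(base = c(0, 0, 0), height = 4),
                      array_pose = rigid_transform(),
                      corridors = NULL,
                      extent = c(-20, 20, -20, 20),
                      seed = 1L) {
  if (is.null(trunks))
    trunks <- data.frame(x = numeric(0), y = numeric(0),
                         radius = numeric(0), height = numeric(0))
  if (!"base_z" %in% names(trunks)) trunks$base_z <- rep(0, nrow(trunks))
  if (nrow(trunks) && any(trunks$radius <= 0))
    stop("trunk radii must be positive")
  if (is.null(foliage))
    foliage <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          sigma = numeric(0), n_points = integer(0))
  structure(list(trunks = trunks, foliage = foliage, lamppost = lamppost,
                 array_pose = array_pose, corridors = corridors,
                 extent = extent, seed = as.integer(seed)),
            class = "bat_scene")
}

#' @export
print.bat_scene <- function(x, ...) {
  cat(sprintf("Scene: %d trunks, %d foliage blobs, lamppost at (%.1f, %.1f), seed %d\n",
              nrow(x$trunks), nrow(x$foliage),
              x$lamppost$base[1], x$lamppost$base[2], x$seed))
  invisible(x)
}

#' Rectangle polygon of a straight corridor
#'
#' @param corridor a corridor element of a [bat_scene()] (`start`, `end`,
#'   `width`).
#' @return List with `x`, `y` polygon vertices (4 corners).
#' @export
corridor_polygon <- function(corridor) {
  s <- corridor$start; e <- corridor$end
  d <- e - s; d <- d / sqrt(sum(d^2))
  n <- c(-d[2], d[1]) * corridor$width / 2
  list(x = c(s[1] + n[1], e[1] + n[1], e[1] - n[1], s[1] - n[1]),
       y = c(s[2] + n[2], e[2] + n[2], e[2] - n[2], s[2] - n[2]))
}

#' Generate a synthetic vegetation point cloud from a scene
#'
#' Emulates a deviation-filtered terrestrial laser scan of the scene:
#' points are sampled uniformly on trunk lateral surfaces (Poisson counts
#' at `density` points per square metre), drawn from each foliage blob's
#' Gaussian, and scattered over the ground plane. Each point receives a
#' pulse-deviation value: a configurable fraction `dev_exceed_frac` of
#' points draws from the "soft return" regime above 15 so the deviation
#' filter has something to remove.
#'
#' @param scene a [bat_scene()].
#' @param density trunk surface point density in points/m^2 (default 400).
#' @param ground_density ground point density in points/m^2 (default 5).
#' @param dev_exceed_frac fraction of points with pulse deviation above 15
#'   (default 0.1).
#' @param seed seed (default the scene's).
#' @return A [point_cloud()] with deviation values.
#' @export
generate_vegetation_cloud <- function(scene, density = 400,
                                      ground_density = 5,
                                      dev_exceed_frac = 0.1,
                                      seed = scene$seed) {
  stopifnot(inherits(scene, "bat_scene"), density >= 0)
  set.seed(seed)
  parts <- list()
  if (nrow(scene$trunks) && density > 0) {
    for (i in seq_len(nrow(scene$trunks))) {
      tr <- scene$trunks[i, ]
      area <- 2 * pi * tr$radius * tr$height
      n <- stats::rpois(1, area * density)
      if (n == 0) next
      th <- stats::runif(n, 0, 2 * pi)
      z <- stats::runif(n, tr$base_z, tr$base_z + tr$height)
      parts[[length(parts) + 1L]] <-
        cbind(tr$x + tr$radius * cos(th), tr$y + tr$radius * sin(th), z)
    }
  }
  if (nrow(scene$foliage)) {
    for (i in seq_len(nrow(scene$foliage))) {
      fb <- scene$foliage[i, ]
      n <- fb$n_points
      if (n == 0) next
      parts[[length(parts) + 1L]] <-
        cbind(stats::rnorm(n, fb$x, fb$sigma),
              stats::rnorm(n, fb$y, fb$sigma),
              stats::rnorm(n, fb$z, fb$sigma))
    }
  }
  if (ground_density > 0) {
    ext <- scene$extent
    area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
    n <- stats::rpois(1, area * ground_density)
    if (n > 0)
      parts[[length(parts) + 1L]] <-
        cbind(stats::runif(n, ext[1], ext[2]),
              stats::runif(n, ext[3], ext[4]),
              stats::rnorm(n, 0, 0.01))
  }
  pts <- if (length(parts)) do.call(rbind, parts) else matrix(numeric(0), 0, 3)
  n <- nrow(pts)
  soft <- stats::runif(n) < dev_exceed_frac
  deviation <- ifelse(soft,
                      sample(16:50, n, replace = TRUE),
                      sample(0:15, n, replace = TRUE))
  point_cloud(pts, deviation = as.numeric(deviation),
              source_id = "synthetic_scan")
}

#' Stamp array reference markers into a cloud
#'
#' Adds a dense, tight blob of points (deviation 0) at each of the array's
#' frame reference points, placed in the scene by the array pose - the
#' synthetic analogue of the reflective frame targets an operator would
#' pick in the scan for co-registration.
#'
#' @param cloud a [point_cloud()].
#' @param array a [mic_array()].
#' @param pose the array pose ([rigid_transform()], array frame to scene
#'   frame).
#' @param points_per_marker points per marker blob (default 60).
#' @param sigma marker blob spread in metres (default 0.004).
#' @param seed seed.
#' @return The augmented [point_cloud()].
#' @export
add_reference_markers <- function(cloud, array, pose,
                                  points_per_marker = 60L, sigma = 0.004,
                                  seed = 1L) {
  set.seed(seed)
  targets <- apply_transform(pose, array$reference_points)
  blobs <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i)
    cbind(stats::rnorm(points_per_marker, targets[i, 1], sigma),
          stats::rnorm(points_per_marker, targets[i, 2], sigma),
          stats::rnorm(points_per_marker, targets[i, 3], sigma))))
  dev <- if (is.null(cloud$deviation)) NULL
         else c(cloud$deviation, rep(0, nrow(blobs)))
  point_cloud(rbind(cloud$points, blobs), deviation = dev,
              source_id = cloud$source_id)
}

#' Pick reference-point correspondences from a marked cloud
#'
#' Emulates the manual picking step: for each frame reference point, takes
#' the centroid of the cloud points within `radius` of its true scene
#' location (the operator knows where the frame is) as the measured target
#' coordinate. The source coordinates are the reference points in the
#' array frame.
#'
#' @param cloud a [point_cloud()] containing marker blobs.
#' @param array a [mic_array()].
#' @param pose the array pose.
#' @param radius picking radius in metres (default 0.03).
#' @return Correspondence data frame (`label`, `src_*`, `dst_*`).
#' @export
pick_reference_correspondences <- function(cloud, array, pose,
                                           radius = 0.03) {
  targets <- apply_transform(pose, array$reference_points)
  src <- array$reference_points
  dst <- matrix(NA_real_, nrow(src), 3)
  for (i in seq_len(nrow(src))) {
    d2 <- colSums((t(cloud$points) - targets[i, ])^2)
    sel <- d2 <= radius^2
    if (!any(sel))
      stop("no marker points found near reference point ",
           rownames(src)[i])
    dst[i, ] <- colMeans(cloud$points[sel, , drop = FALSE])
  }
  data.frame(label = rownames(src),
             src_x = src[, 1], src_y = src[, 2], src_z = src[, 3],
             dst_x = dst[, 1], dst_y = dst[, 2], dst_z = dst[, 3],
             stringsAsFactors = FALSE)
}

#' Does a segment pass through any trunk?
#'
#' Binary occlusion test used by the acoustic forward model: a propagation
#' path from source to microphone is occluded when the 3D segment
#' intersects any trunk cylinder (finite height, vertical axis). Foliage
#' does not occlude.
#'
#' @param p0,p1 segment endpoints (length-3, metres).
#' @param trunks trunk data frame of a [bat_scene()].
#' @return Logical.
#' @export
segment_occluded <- function(p0, p1, trunks) {
  if (is.null(trunks) || nrow(trunks) == 0L) return(FALSE)
  a <- as.numeric(p0); b <- as.numeric(p1)
  d <- b[1:2] - a[1:2]
  for (i in seq_len(nrow(trunks))) {
    cx <- trunks$x[i]; cy <- trunks$y[i]; r <- trunks$radius[i]
    z0 <- trunks$base_z[i]; z1 <- z0 + trunks$height[i]
    f <- a[1:2] - c(cx, cy)
    aa <- sum(d^2); bb <- 2 * sum(f * d); cc <- sum(f^2) - r^2
    if (aa < 1e-12) {                    # vertical segment in XY
      if (cc > 0) next
      t_lo <- 0; t_hi <- 1
    } else {
      disc <- bb^2 - 4 * aa * cc
      if (disc <= 0) next
      sq <- sqrt(disc)
      t_lo <- max(0, (-bb - sq) / (2 * aa))
      t_hi <- min(1, (-bb + sq) / (2 * aa))
      if (t_lo >= t_hi) next
    }
    z_a <- a[3] + t_lo * (b[3] - a[3])
    z_b <- a[3] + t_hi * (b[3] - a[3])
    if (max(z_a, z_b) >= z0 && min(z_a, z_b) <= z1) return(TRUE)
  }
  FALSE
}
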