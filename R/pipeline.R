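#' Demo scenes
#'
#' Two packaged scenes at desk scale. `demo_corridor_scene()`: a straight
#' 7.6 m wide flight corridor between two vegetated edges (trunk rows with
#' foliage), a lamppost inside the corridor and the array standing near the
#' corridor axis - the layout of a forest-edge corridor study.
#' `demo_circling_scene()`: a single prominent trunk 13 m in front of the
#' array with foliage above, around which a bat can circle; the trunk casts
#' an acoustic shadow over the sector behind it as seen from the array.
#'
#' @param seed scene seed.
#' @return A [bat_scene()].
#' @export
demo_corridor_scene <- function(seed = 1L) {
  width <- 7.6
  tx <- seq(-14, 14, by = 2.5)
  trunks <- rbind(
    data.frame(x = tx, y = rep(width / 2 + 0.6, length(tx)),
               radius = 0.22, height = 11),
    data.frame(x = tx + 1.1, y = rep(-width / 2 - 0.6, length(tx)),
               radius = 0.22, height = 11)
  )
  foliage <- rbind(
    data.frame(x = tx, y = width / 2 + 1.2, z = 7.5, sigma = 1.3,
               n_points = 4000L),
    data.frame(x = tx + 1.1, y = -width / 2 - 1.2, z = 7.5, sigma = 1.3,
               n_points = 4000L)
  )
  pose <- rigid_transform(rotation_z(25 * pi / 180), c(0.6, 0.4, 1.2))
  bat_scene(
    trunks = trunks, foliage = foliage,
    lamppost = list(base = c(5, -1.2, 0), height = 4),
    array_pose = pose,
    corridors = list(wide = list(start = c(-14, 0), end = c(14, 0),
                                 width = width)),
    extent = c(-18, 18, -10, 10), seed = seed)
}

#' @rdname demo_corridor_scene
#' @export
demo_circling_scene <- function(seed = 1L) {
  trunks <- data.frame(
    x = c(0, -7, 8), y = c(13, 8, 9),
    radius = c(0.45, 0.25, 0.25), height = c(12, 10, 10))
  foliage <- data.frame(
    x = c(0, -7, 8), y = c(13, 8, 9), z = c(8, 7, 7),
    sigma = c(1.6, 1.1, 1.1), n_points = c(6000L, 3000L, 3000L))
  pose <- rigid_transform(diag(3), c(0, 0, 1.2))
  bat_scene(trunks = trunks, foliage = foliage,
            lamppost = list(base = c(-6, 2, 0), height = 4),
            array_pose = pose, extent = c(-15, 15, -5, 20), seed = seed)
}

#' Rotation about the z axis
#'
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_z <- function(angle) {
  ca <- cos(angle); sa <- sin(angle)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes every stage of the workflow on a simulated scene and keeps the
#' ground truth for scoring: flight-path and recording synthesis, call
#' detection, TOAD estimation by cross-correlation, multilateration with
#' error assessment, position filtering, track building, rigid-body
#' co-registration into the scene frame (from the array reference markers
#' stamped into the synthetic scan), vegetation-cloud deviation filtering
#' and voxelisation, distance-to-structure metrics, and - when corridor
#' polygons assign at least two groups - the corridor comparison
#' statistics.
#'
#' @param scenario `"corridor"` or `"circling"`, or a [bat_scene()].
#' @param config a [run_config()]; its seed drives every random stage.
#' @param path optional pre-built [generate_flight_path()] result;
#'   by default a corridor or circling path matching the scenario.
#' @param verbose print stage progress.
#' @return A list of class `batlas_pipeline` with elements `scene`,
#'   `truth`, `detections`, `positions` (array frame, filtered),
#'   `positions_scene`, `tracks`, `transform`, `grid`, `veg_voxels`,
#'   `distances`, `comparison` (or NULL), and `scores` (recall and
#'   accuracy against ground truth; see Details).
#'
#' @details `scores` reports: `n_emitted`, `n_scorable` (emitted calls
#'   with all channels visible and true range 2-20 m from the array
#'   centre), `n_localised`, `recall` (fraction of scorable calls
#'   recovered within 0.3 m), `mean_position_error_m` over matches,
#'   `mean_dist_veg_recovered` / `mean_dist_veg_truth` (mean
#'   distance-to-vegetation of recovered vs scorable true positions) and
#'   `bat_passes`.
#' @export
run_end_to_end <- function(scenario = "corridor", config = run_config(),
                           path = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  seed <- config$seed
  array <- default_array()
  scene <- if (inherits(scenario, "bat_scene")) scenario
           else switch(scenario,
                       corridor = demo_corridor_scene(seed),
                       circling = demo_circling_scene(seed),
                       stop("unknown scenario: ", scenario))
  if (is.null(path)) {
    kind <- if (!is.null(scene$corridors)) "corridor" else "circle"
    path <- generate_flight_path(kind, scene, duration = config$duration,
                                 call_rate = config$call_rate,
                                 speed = config$speed, seed = seed)
  }
  say("synthesising recording (", nrow(path), " calls)")
  sim <- synthesise_recording(path, array, scene,
                              sample_rate = config$sample_rate,
                              c_sound = config$c_sound,
                              snr_db = config$snr_db, seed = seed + 1L)
  say("detecting calls")
  dets <- detect_calls(sim$recording, band = config$band,
                       threshold = config$detect_threshold,
                       holdoff = config$holdoff)
  say(nrow(dets), " detections; estimating TOADs and localising")
  pos_list <- vector("list", nrow(dets))
  for (i in seq_len(nrow(dets))) {
    ts <- estimate_toads(sim$recording, dets[i, ], array,
                         band = config$band, c_sound = config$c_sound)
    if (ts$n_valid < 3L) next              # < 4 mics incl. reference
    p <- try(localise(ts, array, c_sound = config$c_sound), silent = TRUE)
    if (!inherits(p, "try-error")) pos_list[[i]] <- p
  }
  pos_raw <- do.call(rbind, pos_list[!vapply(pos_list, is.null, TRUE)])
  if (is.null(pos_raw)) pos_raw <- bat_positions(
    data.frame(time = numeric(0), x = numeric(0), y = numeric(0),
               z = numeric(0)))
  class(pos_raw) <- c("bat_positions", "data.frame")
  attr(pos_raw, "frame") <- "array"
  positions <- filter_positions(pos_raw, min_range = config$min_range,
                                max_error = config$max_error)
  say(nrow(positions), " positions survive filtering; building tracks")
  tracks <- build_tracks(positions, max_gap = config$max_gap,
                         max_speed = config$max_speed,
                         min_positions = config$min_positions)
  say("generating vegetation cloud and registering frames")
  cloud <- generate_vegetation_cloud(scene, density = config$scan_density,
                                     seed = seed + 2L)
  cloud <- add_reference_markers(cloud, array, scene$array_pose,
                                 seed = seed + 3L)
  cloud_f <- filter_deviation(cloud, max_dev = config$max_dev)
  corr <- pick_reference_correspondences(cloud_f, array, scene$array_pose)
  tf <- fit_rigid_transform(corr)
  positions_scene <- apply_transform(tf, positions, frame = "scene")
  grid <- voxelise(cloud_f, edge = config$voxel_edge)
  veg <- vegetation_voxels(grid, min_count = config$min_count)
  say(nrow(veg), " vegetation voxels; computing distances")
  distances <- data.frame(
    time = positions_scene$time,
    dist_vegetation = distance_to_vegetation(positions_scene, veg),
    dist_lamppost = distance_to_lamppost(positions_scene,
                                         scene$lamppost$base))
  comparison <- NULL
  if (!is.null(scene$corridors) && nrow(positions_scene)) {
    lab <- rep(NA_character_, nrow(positions_scene))
    for (nm in names(scene$corridors)) {
      poly <- corridor_polygon(scene$corridors[[nm]])
      inside <- point_in_polygon(positions_scene$x, positions_scene$y,
                                 poly$x, poly$y)
      lab[inside & is.na(lab)] <- nm
    }
    distances$label <- lab
    labelled <- !is.na(lab)
    if (length(unique(lab[labelled])) >= 2L)
      comparison <- corridor_comparison(distances[labelled, ])
  }
  scores <- score_against_truth(positions_scene, sim$truth, array, scene,
                                veg, config)
  structure(list(scene = scene, truth = sim$truth, detections = dets,
                 positions = positions, positions_scene = positions_scene,
                 tracks = tracks, transform = tf, grid = grid,
                 veg_voxels = veg, distances = distances,
                 comparison = comparison, scores = scores),
            class = "batlas_pipeline")
}

# compare recovered scene-frame positions with the simulator's truth
score_against_truth <- function(positions_scene, truth, array, scene, veg,
                                config) {
  inv <- invert_transform(scene$array_pose)
  truth_arr <- apply_transform(inv, as.matrix(truth[, c("x", "y", "z")]))
  rng <- sqrt(rowSums(sweep(truth_arr, 2, array$centre)^2))
  scorable <- truth$n_visible == nrow(array$mic_positions) &
    rng >= config$min_range & rng <= 20
  n_loc <- 0L; errs <- numeric(0)
  match_tol <- 0.5 / config$call_rate
  if (nrow(positions_scene) && any(scorable)) {
    for (i in which(scorable)) {
      k <- which(abs(positions_scene$time - truth$time[i]) < match_tol)
      if (!length(k)) next
      d <- sqrt((positions_scene$x[k] - truth$x[i])^2 +
                  (positions_scene$y[k] - truth$y[i])^2 +
                  (positions_scene$z[k] - truth$z[i])^2)
      j <- which.min(d)
      errs <- c(errs, d[j])
      if (d[j] <= 0.3) n_loc <- n_loc + 1L
    }
  }
  truth_dist <- if (any(scorable) && nrow(veg))
    mean(distance_to_vegetation(
      as.matrix(truth[scorable, c("x", "y", "z")]), veg)) else NA_real_
  rec_dist <- if (nrow(positions_scene) && nrow(veg))
    mean(distance_to_vegetation(positions_scene, veg)) else NA_real_
  list(n_emitted = nrow(truth), n_scorable = sum(scorable),
       n_localised = n_loc,
       recall = if (sum(scorable)) n_loc / sum(scorable) else NA_real_,
       mean_position_error_m = if (length(errs)) mean(errs) else NA_real_,
       mean_dist_veg_recovered = rec_dist,
       mean_dist_veg_truth = truth_dist,
       bat_passes = count_bat_passes(positions_scene))
}

#' @export
print.batlas_pipeline <- function(x, ...) {
  s <- x$scores
  cat("End-to-end pipeline result\n")
  cat(sprintf("  emitted calls: %d, scorable: %d, localised within 0.3 m: %d (recall %.1f%%)\n",
              s$n_emitted, s$n_scorable, s$n_localised, 100 * s$recall))
  cat(sprintf("  mean position error: %.3f m; filtered positions: %d; tracks: %d\n",
              s$mean_position_error_m, nrow(x$positions),
              length(unique(x$tracks$track_id))))
  cat(sprintf("  registration RMSD: %.4f m; vegetation voxels: %d\n",
              attr(x$transform, "rmsd"), nrow(x$veg_voxels)))
  cat(sprintf("  mean distance to vegetation: recovered %.2f m, truth %.2f m\n",
              s$mean_dist_veg_recovered, s$mean_dist_veg_truth))
  invisible(x)
}
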