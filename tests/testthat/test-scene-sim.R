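test_that("segment-trunk occlusion agrees with dense sampling", {
  set.seed(80)
  trunks <- data.frame(x = c(0, 3), y = c(5, -2), radius = c(0.4, 0.25),
                       height = c(8, 6), base_z = 0)
  dense_oracle <- function(p0, p1) {
    L <- sqrt(sum((p1 - p0)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(L / 0.001)))
    pts <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]),
                 p0[3] + t * (p1[3] - p0[3]))
    for (i in seq_len(nrow(trunks))) {
      inxy <- (pts[, 1] - trunks$x[i])^2 + (pts[, 2] - trunks$y[i])^2 <
        trunks$radius[i]^2
      inz <- pts[, 3] >= trunks$base_z[i] &
        pts[, 3] <= trunks$base_z[i] + trunks$height[i]
      if (any(inxy & inz)) return(TRUE)
    }
    FALSE
  }
  n_occ <- 0L
  for (i in 1:300) {
    p0 <- c(runif(1, -2, 5), runif(1, -4, 8), runif(1, 0, 9))
    p1 <- p0 + runif(3, -1, 1) * c(4, 4, 3)
    got <- segment_occluded(p0, p1, trunks)
    expect_equal(got, dense_oracle(p0, p1), info = paste("segment", i))
    n_occ <- n_occ + got
  }
  expect_gt(n_occ, 5)          # the sample actually exercises both branches
})

test_that("vegetation cloud sampling matches analytic expectations", {
  scene <- bat_scene(
    trunks = data.frame(x = 0, y = 0, radius = 0.3, height = 10),
    extent = c(-1, 1, -1, 1), seed = 7)
  # zero density and no ground: empty
  empty <- generate_vegetation_cloud(scene, density = 0, ground_density = 0)
  expect_equal(nrow(empty$points), 0L)
  # Poisson count: area x density within 5%
  density <- 1000
  cloud <- generate_vegetation_cloud(scene, density = density,
                                     ground_density = 0,
                                     dev_exceed_frac = 0)
  expected <- 2 * pi * 0.3 * 10 * density
  expect_lt(abs(nrow(cloud$points) - expected) / expected, 0.05)
  # all points on the cylinder surface
  r <- sqrt(cloud$points[, 1]^2 + cloud$points[, 2]^2)
  expect_lt(max(abs(r - 0.3)), 1e-9)
  expect_true(all(cloud$points[, 3] >= 0 & cloud$points[, 3] <= 10))
})

test_that("the soft-return fraction matches the configured probability", {
  scene <- bat_scene(
    trunks = data.frame(x = 0, y = 0, radius = 0.5, height = 10),
    extent = c(-1, 1, -1, 1), seed = 8)
  cloud <- generate_vegetation_cloud(scene, density = 3200,
                                     ground_density = 0,
                                     dev_exceed_frac = 0.1)
  n <- nrow(cloud$points)
  expect_gt(n, 5e4)
  frac <- mean(cloud$deviation > 15)
  expect_lt(abs(frac - 0.1), 0.02)
  # and the deviation filter then removes exactly those points
  expect_equal(nrow(filter_deviation(cloud)$points), sum(!(cloud$deviation > 15)))
})

test_that("identical seeds reproduce clouds and recordings byte for byte", {
  scene <- demo_circling_scene(seed = 5)
  c1 <- generate_vegetation_cloud(scene, density = 50, seed = 5)
  c2 <- generate_vegetation_cloud(scene, density = 50, seed = 5)
  expect_identical(c1$points, c2$points)
  expect_identical(c1$deviation, c2$deviation)
  path <- generate_flight_path("circle", scene, duration = 1,
                               call_rate = 5, seed = 5)
  arr <- default_array()
  s1 <- synthesise_recording(path, arr, scene, seed = 5)
  s2 <- synthesise_recording(path, arr, scene, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".wav")
  f2 <- withr::local_tempfile(fileext = ".wav")
  write_wav(s1$recording, f1); write_wav(s2$recording, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("flight paths honour their geometric contracts", {
  scene <- demo_circling_scene(seed = 9)
  circ <- generate_flight_path("circle", scene, duration = 10,
                               call_rate = 10, standoff = 2, seed = 9)
  expect_equal(nrow(circ), 100L)            # duration x call rate events
  tr <- scene$trunks[1, ]
  d_axis <- sqrt((circ$x - tr$x)^2 + (circ$y - tr$y)^2)
  expect_true(all(abs(d_axis - 2) < 0.2))
  expect_true(all(diff(circ$time) > 0))

  cscene <- demo_corridor_scene(seed = 9)
  corr <- generate_flight_path("corridor", cscene, duration = 12,
                               call_rate = 8, seed = 9)
  poly <- corridor_polygon(cscene$corridors$wide)
  expect_true(all(point_in_polygon(corr$x, corr$y, poly$x, poly$y)))
  # implied speeds stay in the plausible band
  sp <- sqrt(diff(corr$x)^2 + diff(corr$y)^2 + diff(corr$z)^2) /
    diff(corr$time)
  expect_true(all(sp <= 15 + 1e-9))
  expect_error(generate_flight_path("circle", scene, speed = 30),
               "1-15 m/s")
  expect_error(generate_flight_path("glide", scene), "arg")
})

test_that("without trunks every channel receives every call", {
  scene <- bat_scene(extent = c(-5, 5, -5, 5), seed = 10,
                     array_pose = rigid_transform(diag(3), c(0, 0, 1)))
  path <- generate_flight_path("random-walk", scene, duration = 1,
                               call_rate = 5, seed = 10)
  sim <- synthesise_recording(path, default_array(), scene, seed = 10)
  expect_true(all(sim$truth$n_visible == 8L))
  expect_true(all(sim$truth$occluded == ""))
})

test_that("a source right behind a trunk is fully occluded (acoustic shadow)", {
  scene <- demo_circling_scene(seed = 11)
  tr <- scene$trunks[1, ]
  behind <- data.frame(time = 0, x = tr$x, y = tr$y + tr$radius + 1.5,
                       z = 4)
  class(behind) <- c("true_path", "data.frame")
  sim <- synthesise_recording(behind, default_array(), scene, seed = 11)
  expect_equal(sim$truth$n_visible, 0L)
  # nothing beyond noise on any channel (a direct call at this range
  # would peak near 1/15 ~ 0.066)
  expect_lt(max(abs(sim$recording$samples)), 0.025)
})

test_that("synthetic propagation delays match geometric TOADs", {
  arr <- default_array()
  scene <- bat_scene(extent = c(-5, 5, -5, 5), seed = 12,
                     array_pose = rigid_transform())  # identity pose
  src <- c(4, 3, 5)
  path <- data.frame(time = 0.02, x = src[1], y = src[2], z = src[3])
  class(path) <- c("true_path", "data.frame")
  sim <- synthesise_recording(path, arr, scene, snr_db = 60, seed = 12)
  det <- detect_calls(sim$recording)
  expect_equal(nrow(det), 1L)
  ts <- estimate_toads(sim$recording, det[1, ], arr)
  geo <- theoretical_toads(src, arr)
  expect_true(all(abs(ts$toads - geo) * 300e3 < 0.2))
})

test_that("localisation recall degrades as SNR drops", {
  scene <- bat_scene(extent = c(-8, 8, -8, 8), seed = 13,
                     array_pose = rigid_transform(diag(3), c(0, 0, 1)))
  arr <- default_array()
  path <- generate_flight_path("random-walk", scene, duration = 2,
                               call_rate = 5, seed = 13)
  # ground truth in the array frame (localise works there)
  truth_arr <- apply_transform(invert_transform(scene$array_pose),
                               as.matrix(path[, c("x", "y", "z")]))
  recall_at <- function(snr) {
    sim <- synthesise_recording(path, arr, scene, snr_db = snr, seed = 13)
    det <- detect_calls(sim$recording)
    hits <- 0L
    for (i in seq_len(nrow(det))) {
      ts <- try(estimate_toads(sim$recording, det[i, ], arr),
                silent = TRUE)
      if (inherits(ts, "try-error") || ts$n_valid < 3L) next
      p <- try(localise(ts, arr), silent = TRUE)
      if (inherits(p, "try-error") || !p$valid) next
      d <- sqrt((p$x - truth_arr[, 1])^2 + (p$y - truth_arr[, 2])^2 +
                  (p$z - truth_arr[, 3])^2)
      if (min(d) < 0.5) hits <- hits + 1L
    }
    hits / nrow(path)
  }
  r <- vapply(c(40, 10, -10), recall_at, numeric(1))
  expect_true(all(diff(r) <= 0))
  expect_gt(r[1], 0.8)
  expect_lt(r[3], r[1])
})
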