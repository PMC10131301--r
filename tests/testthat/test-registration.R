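ref5 <- default_array()$reference_points

test_that("identical point sets give the identity transform", {
  tf <- fit_rigid_transform(ref5, ref5)
  expect_equal(tf$rotation, diag(3), tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_lt(attr(tf, "rmsd"), 1e-12)
})

test_that("a known rotation + translation is recovered exactly", {
  R <- rotation_z(30 * pi / 180)
  t_true <- c(1, 2, 0.5)
  target <- ref5 %*% t(R) + matrix(t_true, 5, 3, byrow = TRUE)
  tf <- fit_rigid_transform(ref5, target)
  expect_lt(attr(tf, "rmsd"), 1e-9)
  expect_lt(max(abs(tf$rotation - R)), 1e-9)
  expect_lt(max(abs(tf$translation - t_true)), 1e-9)
})

test_that("1 cm target noise keeps the typical rotation error under 1 degree", {
  set.seed(60)
  angs <- replicate(25, {
    R <- random_rotation()
    t_true <- rnorm(3, 0, 5)
    target <- ref5 %*% t(R) + matrix(t_true, 5, 3, byrow = TRUE) +
      matrix(rnorm(15, 0, 0.01), 5, 3)
    tf <- fit_rigid_transform(target = target, source = ref5)
    expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
    rotation_angle_deg(t(R) %*% tf$rotation)
  })
  expect_lt(median(angs), 1)
})

test_that("reflections are never returned even when they fit better", {
  mirrored <- ref5 %*% diag(c(1, 1, -1))
  # the poor fit of a forced proper rotation triggers the RMSD QC warning
  expect_warning(tf <- fit_rigid_transform(ref5, mirrored), "RMSD")
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(tf, "rmsd"), 0.1)
})

test_that("degenerate correspondence sets are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_rigid_transform(line, line + 1), "collinear")
  expect_error(fit_rigid_transform(ref5[1:2, ], ref5[1:2, ]), "3 point")
  dup <- ref5; dup[2, ] <- dup[1, ]
  expect_error(fit_rigid_transform(dup, dup), "duplicated")
})

test_that("fitting is invariant under a common rigid motion", {
  set.seed(61)
  target <- ref5 %*% t(rotation_z(0.4)) +
    matrix(c(3, -1, 2), 5, 3, byrow = TRUE) +
    matrix(rnorm(15, 0, 0.02), 5, 3)
  base <- attr(fit_rigid_transform(ref5, target), "rmsd")
  Rc <- random_rotation(); tc <- rnorm(3)
  move <- function(m) m %*% t(Rc) + matrix(tc, nrow(m), 3, byrow = TRUE)
  moved <- attr(fit_rigid_transform(move(ref5), move(target)), "rmsd")
  expect_equal(moved, base, tolerance = 1e-9)
})

test_that("reported RMSD equals brute-force residual recomputation", {
  set.seed(62)
  target <- ref5 %*% t(random_rotation()) +
    matrix(rnorm(3), 5, 3, byrow = TRUE) + matrix(rnorm(15, 0, 0.05), 5, 3)
  tf <- suppressWarnings(fit_rigid_transform(ref5, target))
  mapped <- apply_transform(tf, ref5)
  expect_equal(attr(tf, "rmsd"),
               sqrt(mean(rowSums((target - mapped)^2))), tolerance = 1e-12)
})

test_that("rigid application preserves distances and inverts cleanly", {
  set.seed(63)
  tf <- fit_rigid_transform(ref5, ref5 %*% t(rotation_z(1)) +
                              matrix(c(5, 5, 0), 5, 3, byrow = TRUE))
  pts <- matrix(rnorm(30, 0, 5), 10, 3)
  moved <- apply_transform(tf, pts)
  expect_equal(as.matrix(dist(moved)), as.matrix(dist(pts)),
               tolerance = 1e-9)
  back <- apply_transform(invert_transform(tf), moved)
  expect_lt(max(abs(back - pts)), 1e-9)
  # identity transform leaves positions untouched, errors carried over
  pos <- toy_positions(c(5, 8), radial = c(0.1, 0.2),
                       tangential = c(0.1, 0.2))
  same <- apply_transform(rigid_transform(), pos)
  expect_equal(same$x, pos$x)
  expect_equal(same$radial_error, pos$radial_error)
  expect_equal(attr(same, "frame"), "scene")
})

test_that("transforms and correspondences round-trip through files", {
  tf <- rigid_transform(rotation_z(0.7), c(1.25, -2.5, 0.125))
  path <- withr::local_tempfile(fileext = ".json")
  write_transform(tf, path)
  back <- read_transform(path)
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(back$translation, tf$translation, tolerance = 1e-12)
  corr <- data.frame(label = rownames(ref5),
                     src_x = ref5[, 1], src_y = ref5[, 2], src_z = ref5[, 3],
                     dst_x = ref5[, 1] + 1, dst_y = ref5[, 2],
                     dst_z = ref5[, 3])
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_correspondences(corr, cpath)
  back2 <- read_correspondences(cpath)
  expect_equal(back2$dst_x, corr$dst_x)
  tf2 <- fit_rigid_transform(back2)
  expect_equal(tf2$translation, c(1, 0, 0), tolerance = 1e-9)
})

test_that("improper rotations cannot construct a transform", {
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
})
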