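test_that("XYZ CSV clouds load and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "0,0,0", "1.5,2.25,3.125", "-1,0.5,2"), path)
  cloud <- load_point_cloud(path)
  expect_equal(nrow(cloud$points), 3L)
  expect_null(cloud$deviation)
  out <- withr::local_tempfile(fileext = ".csv")
  set.seed(50)
  cloud2 <- point_cloud(matrix(runif(30, -5, 5), 10, 3),
                        deviation = sample(0:30, 10), source_id = "t")
  write_point_cloud(cloud2, out)
  back <- load_point_cloud(out)
  expect_lt(max(abs(back$points - cloud2$points)), 1e-6)
  expect_equal(back$deviation, as.numeric(cloud2$deviation))
})

test_that("malformed records and missing deviation error informatively", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", "0,0,0", "1,oops,2"), path)
  expect_error(load_point_cloud(path), "line 2")
  expect_error(load_point_cloud(withr::local_tempfile()), "not found")
  cloud <- point_cloud(matrix(0, 2, 3))
  expect_error(filter_deviation(cloud), "deviation")
})

test_that("the deviation filter keeps 15 and removes 16", {
  cloud <- point_cloud(matrix(rnorm(9), 3, 3), deviation = c(0, 15, 16))
  kept <- filter_deviation(cloud)
  expect_equal(nrow(kept$points), 2L)
  expect_equal(kept$deviation, c(0, 15))
  # all-zero deviation: identity
  cl2 <- point_cloud(matrix(rnorm(9), 3, 3), deviation = c(0, 0, 0))
  expect_equal(nrow(filter_deviation(cl2)$points), 3L)
  # empty cloud passes through
  cl3 <- point_cloud(matrix(numeric(0), 0, 3), deviation = numeric(0))
  expect_equal(nrow(filter_deviation(cl3)$points), 0L)
})

test_that("points in one cell produce a single voxel with the full count", {
  set.seed(51)
  pts <- matrix(runif(36, 0.41, 0.59), 12, 3)
  grid <- voxelise(point_cloud(pts), edge = 0.2, origin = c(0, 0, 0))
  expect_equal(nrow(grid$index), 1L)
  expect_equal(grid$counts, 12L)
  expect_equal(grid$index[1, ], c(2L, 2L, 2L), ignore_attr = TRUE)
})

test_that("boundary points fall in the higher-index cell", {
  grid <- voxelise(point_cloud(rbind(c(0.2, 0, 0))), edge = 0.2,
                   origin = c(0, 0, 0))
  expect_equal(grid$index[1, 1], 1L)
})

test_that("voxel counts are conserved and order-independent", {
  set.seed(52)
  pts <- matrix(runif(30000, -7, 13), 10000, 3)
  origin <- runif(3, -2, 0)
  grid <- voxelise(point_cloud(pts), edge = 0.2, origin = origin)
  expect_equal(sum(grid$counts), 10000L)
  perm <- voxelise(point_cloud(pts[sample(10000), ]), edge = 0.2,
                   origin = origin)
  o1 <- order(grid$index[, 1], grid$index[, 2], grid$index[, 3])
  o2 <- order(perm$index[, 1], perm$index[, 2], perm$index[, 3])
  expect_equal(grid$index[o1, ], perm$index[o2, ])
  expect_equal(grid$counts[o1], perm$counts[o2])
})

test_that("deviation filtering commutes with voxel totals", {
  set.seed(53)
  pts <- matrix(runif(3000, 0, 5), 1000, 3)
  dev <- sample(0:30, 1000, replace = TRUE)
  cloud <- point_cloud(pts, deviation = dev)
  filtered <- filter_deviation(cloud)
  grid <- voxelise(filtered, edge = 0.25, origin = c(0, 0, 0))
  expect_equal(sum(grid$counts), sum(dev <= 15))
})

test_that("vegetation voxels use an inclusive 10-point threshold", {
  # three cells holding 9, 10 and 11 points
  pts <- rbind(
    matrix(rep(c(0.1, 0.1, 0.1), 9), ncol = 3, byrow = TRUE),
    matrix(rep(c(0.5, 0.1, 0.1), 10), ncol = 3, byrow = TRUE),
    matrix(rep(c(0.9, 0.1, 0.1), 11), ncol = 3, byrow = TRUE))
  grid <- voxelise(point_cloud(pts), edge = 0.2, origin = c(0, 0, 0))
  expect_equal(nrow(vegetation_voxels(grid, min_count = 10)), 2L)
  expect_equal(nrow(vegetation_voxels(grid, min_count = 1)), 3L)
  empty <- voxelise(point_cloud(matrix(numeric(0), 0, 3)))
  expect_equal(nrow(vegetation_voxels(empty)), 0L)
})

test_that("raising min_count never enlarges the vegetation set", {
  set.seed(54)
  grid <- voxelise(point_cloud(matrix(runif(6000, 0, 3), 2000, 3)),
                   edge = 0.3)
  sizes <- vapply(1:12, function(k) nrow(vegetation_voxels(grid, k)),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("voxel grids round-trip through CSV", {
  set.seed(55)
  grid <- voxelise(point_cloud(matrix(runif(300, -4, 4), 100, 3)),
                   edge = 0.2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_voxel_grid(grid, path)
  back <- read_voxel_grid(path)
  expect_equal(back$origin, grid$origin, tolerance = 1e-9)
  expect_equal(back$edge, grid$edge)
  expect_equal(back$index, grid$index, ignore_attr = TRUE)
  expect_equal(back$counts, grid$counts)
})
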