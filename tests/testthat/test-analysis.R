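test_that("nearest-vegetation distances match simple geometry", {
  veg <- rbind(c(1, 0, 0))
  expect_equal(distance_to_vegetation(rbind(c(1, 0, 0)), veg), 0)
  expect_equal(distance_to_vegetation(rbind(c(4, 4, 0)), veg), 5)
  expect_error(distance_to_vegetation(rbind(c(0, 0, 0)),
                                      matrix(numeric(0), 0, 3)),
               "undefined")
})

test_that("the spatial index equals brute force", {
  set.seed(70)
  q <- matrix(runif(300 * 3, -20, 20), 300, 3)
  v <- matrix(runif(200 * 3, -20, 20), 200, 3)
  expect_equal(distance_to_vegetation(q, v, method = "index"),
               distance_to_vegetation(q, v, method = "brute"),
               tolerance = 1e-12)
})

test_that("NN distances are invariant under a common rigid transform", {
  set.seed(71)
  q <- matrix(runif(60, -10, 10), 20, 3)
  v <- matrix(runif(150, -10, 10), 50, 3)
  base <- distance_to_vegetation(q, v)
  tf <- rigid_transform(random_rotation(), rnorm(3, 0, 10))
  expect_equal(distance_to_vegetation(apply_transform(tf, q),
                                      apply_transform(tf, v)),
               base, tolerance = 1e-9)
})

test_that("adding vegetation voxels can only reduce distances", {
  set.seed(72)
  q <- matrix(runif(60, -10, 10), 20, 3)
  v1 <- matrix(runif(60, -10, 10), 20, 3)
  v2 <- rbind(v1, matrix(runif(60, -10, 10), 20, 3))
  expect_true(all(distance_to_vegetation(q, v2) <=
                    distance_to_vegetation(q, v1) + 1e-12))
})

test_that("lamppost distances follow the chosen convention", {
  base <- c(0, 0, 0)
  expect_equal(distance_to_lamppost(rbind(c(0, 0, 7)), base), 0)
  for (z in c(0, 4, 9))
    expect_equal(distance_to_lamppost(rbind(c(3, 4, z)), base), 5)
  expect_equal(distance_to_lamppost(rbind(c(0, 3, 8)), base, mode = "3d",
                                    height = 4), 5)
})

test_that("Welch t follows the formula", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  wt <- welch_t(a, b)
  expect_equal(wt$statistic, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(welch_t(b, a)$statistic, -wt$statistic)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(1, 1)), "zero variance")
})

test_that("KS D follows the ECDF definition", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), 1.5)$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "at least 1")
})

test_that("Welch t and KS D match the reference implementations", {
  set.seed(73)
  for (i in 1:50) {
    a <- rnorm(sample(5:60, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    wt <- welch_t(a, b)
    tt <- t.test(a, b)
    expect_equal(wt$statistic, unname(tt$statistic), tolerance = 1e-9)
    expect_equal(wt$df, unname(tt$parameter), tolerance = 1e-9)
    expect_equal(wt$p_value, tt$p.value, tolerance = 1e-9)
    ks <- ks_two_sample(a, b)
    expect_equal(ks$statistic, unname(ks.test(a, b)$statistic),
                 tolerance = 1e-9)
  }
})

test_that("corridor comparison recovers a known group separation", {
  set.seed(74)
  n <- 1000
  d <- data.frame(
    dist_vegetation = c(rnorm(n, 4, 0.5), rnorm(n, 3, 0.5)),
    dist_lamppost = c(rnorm(n, 4.2, 0.5), rnorm(n, 3.1, 0.5)),
    label = rep(c("wide", "narrow"), each = n))
  cmp <- corridor_comparison(d)
  s <- cmp$summary
  diff_means <- s$mean_dist_vegetation[s$label == "wide"] -
    s$mean_dist_vegetation[s$label == "narrow"]
  expect_lt(abs(diff_means - 1), 0.1)
  bw <- cmp$tests[cmp$tests$kind == "between-group" &
                    cmp$tests$metric == "dist_vegetation", ]
  expect_gt(abs(bw$welch_t), 2)
  expect_lt(bw$welch_p, 0.001)
})

test_that("identical groups give null statistics", {
  set.seed(75)
  x <- rnorm(50, 4)
  d <- data.frame(dist_vegetation = c(x, x), dist_lamppost = c(x, x) + 0.5,
                  label = rep(c("a", "b"), each = 50))
  cmp <- corridor_comparison(d)
  bw <- cmp$tests[cmp$tests$kind == "between-group", ]
  expect_true(all(bw$welch_t == 0))
  expect_true(all(bw$ks_d == 0))
})

test_that("a single group yields summaries but no between-group tests", {
  d <- data.frame(dist_vegetation = rnorm(20, 4),
                  dist_lamppost = rnorm(20, 3))
  cmp <- corridor_comparison(d)
  expect_equal(nrow(cmp$summary), 1L)
  expect_false(any(cmp$tests$kind == "between-group"))
  # undersized groups are excluded from tests with a warning
  d2 <- rbind(d, data.frame(dist_vegetation = 1, dist_lamppost = 1))
  d2$label <- c(rep("big", 20), "tiny")
  expect_warning(corridor_comparison(d2), "fewer than 2")
})

test_that("point-in-polygon assigns corridor membership", {
  poly <- corridor_polygon(list(start = c(0, 0), end = c(10, 0),
                                width = 4))
  expect_true(point_in_polygon(5, 1.9, poly$x, poly$y))
  expect_false(point_in_polygon(5, 2.5, poly$x, poly$y))
  expect_false(point_in_polygon(-1, 0, poly$x, poly$y))
})
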