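test_that("point cloud loaders round-trip and reject junk", {
  cn <- make_canopy(canopy_spec("box", c(5, 5, 4), point_density = 4,
                                seed = 1))
  ply <- file.path(tempdir(), "c.ply")
  xyz <- file.path(tempdir(), "c.xyz")
  write_ply(cn$cloud, ply)
  write_xyz(cn$cloud, xyz)
  expect_equal(read_ply(ply)$points, cn$cloud$points, tolerance = 1e-12)
  expect_equal(load_points(xyz)$points, cn$cloud$points,
               tolerance = 1e-12)

  empty <- file.path(tempdir(), "empty.xyz")
  file.create(empty)
  expect_error(read_xyz(empty), "empty|parse")
  writeLines(c("1 2 3", "4 5 6", "7 8 9", "1 1 1", "2 2 2"),
             f5 <- file.path(tempdir(), "five.xyz"))
  expect_identical(nrow(read_xyz(f5)$points), 5L)
  writeLines(c("1 2 3", "4 5 6"), f2 <- file.path(tempdir(), "two.xyz"))
  expect_error(load_points(f2), "fewer than 4")
  expect_error(load_points("x.las", format = "las"), "not supported")
})

test_that("remove_outliers removes exactly the planted set", {
  fx <- unit_cube_with_outliers()
  filtered <- remove_outliers(fx$cloud, knn = 16, std_multiplier = 2)
  expect_identical(attr(filtered, "removed"), fx$outlier_idx)

  # statistic matches the brute-force oracle
  stat <- saltFCE:::.knn_mean_dist(fx$cloud$points[1:200, ], 5L)
  expect_equal(stat, brute_knn_stat(fx$cloud$points[1:200, ], 5),
               tolerance = 1e-12)

  # an outlier-free fixture cloud loses at most 2% of its points
  clean <- make_canopy(canopy_spec("box", c(10, 10, 8), point_density = 6,
                                   seed = 2))$cloud
  kept <- remove_outliers(clean, 16, 2)
  expect_lte(1 - nrow(kept$points) / nrow(clean$points), 0.02)

  # huge multiplier = identity
  all_kept <- remove_outliers(fx$cloud, 16, 1e9)
  expect_identical(nrow(all_kept$points), nrow(fx$cloud$points))
  expect_error(remove_outliers(point_cloud(diag(3)), knn = 5),
               "more than knn")
})

test_that("voxel filter collapses only the sub-canopy layer", {
  # all points at the canopy top (zero z range, nothing below the cut)
  # pass through untouched
  set.seed(1)
  top <- point_cloud(cbind(runif(50), runif(50), 10))
  out <- voxel_filter_below_canopy(top, 0.25, 0.5)
  expect_identical(out$points, top$points)

  # 100 coincident low points -> one centroid
  low <- matrix(rep(c(0.1, 0.1, 0.1), each = 100), ncol = 3)
  cl <- point_cloud(rbind(low, c(0, 0, 10)))
  out2 <- voxel_filter_below_canopy(cl, 0.25, 0.5)
  expect_identical(nrow(out2$points), 2L)
  expect_equal(out2$points[2, ], c(x = 0.1, y = 0.1, z = 0.1))

  # monotone point-count reduction on a real fixture
  cn <- make_canopy(canopy_spec("hemisphere", 6, point_density = 6,
                                seed = 3))
  out3 <- voxel_filter_below_canopy(cn$cloud, 0.25, 0.5)
  expect_lte(nrow(out3$points), nrow(cn$cloud$points))
})

test_that("MLS smoothing projects noise back to the surface", {
  set.seed(9)
  g <- expand.grid(x = seq(0, 10, 0.4), y = seq(0, 10, 0.4))
  plane <- point_cloud(cbind(g$x, g$y, 0.5 * g$x + 2))
  sm <- mls_smooth(plane, 1)
  expect_lt(max(abs(sm$points - plane$points)), 1e-6)
  expect_identical(nrow(sm$points), nrow(plane$points))

  noisy <- plane
  noise <- rnorm(nrow(g), 0, 0.2)
  noisy$points[, 3] <- noisy$points[, 3] + noise
  sm2 <- mls_smooth(noisy, 1)
  resid <- (sm2$points[, 3] - 0.5 * sm2$points[, 1] - 2) /
    sqrt(1 + 0.25)  # orthogonal distance to the true plane
  expect_lt(sqrt(mean(resid^2)), sqrt(mean(noise^2)) / 2)

  # isolated point passes through
  iso <- point_cloud(rbind(plane$points, c(50, 50, 50)))
  sm3 <- mls_smooth(iso, 1)
  expect_equal(sm3$points[nrow(sm3$points), ], c(x = 50, y = 50, z = 50))
})

test_that("base_to_ground zeroes the minimum height only", {
  cl <- point_cloud(cbind(1:3, 4:6, c(3, 7, 10)))
  out <- base_to_ground(cl)
  expect_equal(out$points[, 3], c(0, 4, 7))
  expect_equal(out$points[, 1:2], cl$points[, 1:2])
  expect_equal(base_to_ground(out)$points, out$points)
  single <- base_to_ground(point_cloud(matrix(c(1, 2, 5), 1)))
  expect_equal(single$points[1, 3], c(z = 0))
})

test_that("grid height and leaf area follow the stated cell rules", {
  # flat canopy: height independent of cell size
  set.seed(4)
  flat <- point_cloud(cbind(runif(500, 0, 8), runif(500, 0, 8), 12))
  for (cell in c(0.25, 0.5, 2))
    expect_equal(grid_height(flat, cell), 12)

  # two occupied cells with max 10 and 20 -> mean 15
  two <- point_cloud(rbind(c(0.1, 0.1, 10), c(0.2, 0.2, 4),
                           c(1.4, 0.1, 20)))
  expect_equal(grid_height(two, 0.5), 15)

  # single point occupies one cell
  one <- point_cloud(matrix(c(3, 3, 1), 1))
  expect_equal(canopy_leaf_area(one, 0.5), 0.25)

  # points confined to one 0.5 cm cell
  clump <- point_cloud(cbind(runif(40, 0, 0.49), runif(40, 0, 0.49), 1))
  expect_equal(canopy_leaf_area(clump, 0.5), 0.25)

  # dense disk footprint ~ pi r^2 within 5% (cell small versus r, else
  # fully-counted boundary cells dominate the error)
  r <- 6
  set.seed(5)
  th <- runif(20000, 0, 2 * pi); rr <- r * sqrt(runif(20000))
  disk <- point_cloud(cbind(rr * cos(th), rr * sin(th), 1))
  expect_lt(abs(canopy_leaf_area(disk, 0.25) / (pi * r^2) - 1), 0.05)

  # translation by integer cell multiples leaves both traits unchanged
  cn <- make_canopy(canopy_spec("box", c(6, 6, 5), point_density = 6,
                                seed = 6))
  cl <- base_to_ground(cn$cloud)
  moved <- cl; moved$points[, 1] <- moved$points[, 1] + 3 * 0.5
  expect_equal(grid_height(moved, 0.5), grid_height(cl, 0.5))
  expect_equal(canopy_leaf_area(moved, 0.5), canopy_leaf_area(cl, 0.5))

  # adding points never shrinks the area
  more <- point_cloud(rbind(cl$points, c(100, 100, 1)))
  expect_gte(canopy_leaf_area(more, 0.5), canopy_leaf_area(cl, 0.5))
})

test_that("convex hull volume is exact on solids and matches oracles", {
  cube <- point_cloud(as.matrix(expand.grid(c(0, 10), c(0, 10), c(0, 10))))
  expect_equal(convex_hull_volume(cube), 1000)

  a <- 3
  tet <- point_cloud(rbind(c(0, 0, 0), c(a, 0, 0),
                           c(a / 2, a * sqrt(3) / 2, 0),
                           c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3))))
  expect_equal(convex_hull_volume(tet), a^3 / (6 * sqrt(2)))

  # interior points do not change the hull
  set.seed(6)
  filled <- point_cloud(rbind(cube$points, matrix(runif(300, 1, 9), ncol = 3)))
  expect_equal(convex_hull_volume(filled), 1000)

  # rigid motion invariance and s^3 scaling
  set.seed(7)
  pts <- matrix(rnorm(150), ncol = 3)
  v0 <- convex_hull_volume(point_cloud(pts))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(convex_hull_volume(point_cloud(pts %*% R + 5)), v0)
  expect_equal(convex_hull_volume(point_cloud(pts * 2.5)), v0 * 2.5^3)

  # Monte-Carlo point-in-hull oracle on a random cloud
  set.seed(8)
  cl <- point_cloud(matrix(runif(3 * 400, 0, 10), ncol = 3))
  mc <- mc_hull_volume(cl, n = 40000L, seed = 2)
  expect_lt(abs(mc$exact - mc$volume), 3 * mc$se)
  expect_equal(convex_hull_volume(cl), mc$exact)

  expect_error(convex_hull_volume(
    point_cloud(cbind(runif(10), runif(10), 1))), "degenerate")
  expect_error(convex_hull_volume(point_cloud(matrix(1, 3, 3))),
               "at least 4|degenerate")
})

test_that("full pipeline recovers analytic box traits, with and without outliers", {
  clean <- make_canopy(canopy_spec("box", c(20, 20, 15), point_density = 8,
                                   seed = 10))
  st <- extract_structural_traits(clean$cloud)
  expect_lt(abs(st$height / clean$truth$height - 1), 0.05)
  expect_lt(abs(st$canopy_leaf_area / clean$truth$canopy_leaf_area - 1), 0.05)
  expect_lt(abs(st$volume / clean$truth$volume - 1), 0.05)

  dirty <- make_canopy(canopy_spec("box", c(20, 20, 15), point_density = 8,
                                   outlier_count = 10, seed = 10))
  st2 <- extract_structural_traits(dirty$cloud)
  for (f in c("height", "canopy_leaf_area", "volume"))
    expect_lt(abs(st2[[f]] / st[[f]] - 1), 0.05, label = f)

  # taller canopy -> strictly larger height
  tall <- make_canopy(canopy_spec("box", c(20, 20, 25), point_density = 8,
                                  seed = 10))
  expect_gt(extract_structural_traits(tall$cloud)$height, st$height)

  # every reducing stage is non-increasing in point count
  n0 <- nrow(dirty$cloud$points)
  c1 <- remove_outliers(dirty$cloud, 16, 2)
  c2 <- voxel_filter_below_canopy(c1, 0.25, 0.5)
  c3 <- mls_smooth(c2, 1)
  expect_lte(nrow(c1$points), n0)
  expect_lte(nrow(c2$points), nrow(c1$points))
  expect_identical(nrow(c3$points), nrow(c2$points))
})
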