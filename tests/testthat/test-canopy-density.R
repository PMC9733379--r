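test_that("segmentation keeps strictly-above-threshold points", {
  pc <- point_cloud(cbind(1:3, 1:3, 1:3), "LOCAL", e = c(-0.01, 0, 0.3))
  expect_identical(nrow(segment_above_ground(pc)$coords), 1L)
  expect_identical(nrow(segment_above_ground(pc, 0.05)$coords), 1L)
  expect_identical(nrow(segment_above_ground(pc, 0.5)$coords), 0L)
  noe <- point_cloud(cbind(1, 1, 1), "LOCAL")
  expect_error_class(segment_above_ground(noe), "cottoncanopy_validation_error")
})

test_that("estimated-terrain segmentation matches the true-terrain split", {
  f <- small_field()
  # package-side: plane fitted to ground-type points, then threshold on e
  plane <- fit_plane_orthogonal(
    as.matrix(f$local[f$local$type == "ground", c("x", "y", "z")]))
  loc <- relative_heights(point_cloud(as.matrix(f$local[c("x", "y", "z")]),
                                      "LOCAL"), plane)
  kept <- nrow(segment_above_ground(loc, 0.05)$coords)
  # generator-side: the same rule on the true relative heights
  true_frac <- mean(f$local$e > 0.05)
  expect_lt(abs(kept / nrow(loc$coords) - true_frac), 0.01)
  # and nearly all kept points are genuine plant points
  keep_idx <- loc$e > 0.05
  expect_gt(mean(f$local$type[keep_idx] != "ground"), 0.99)
})

test_that("density grid scales counts by the inverse squared cell size", {
  one <- density_grid(point_cloud(rbind(c(0.4, 0, 0.3)), "LOCAL", e = 0.3),
                      epsilon = 1)
  expect_identical(dim(one$a), c(1L, 1L))
  expect_equal(one$a[1, 1], 1)
  half <- density_grid(point_cloud(rbind(c(0.4, 0, 0.3)), "LOCAL", e = 0.3),
                       epsilon = 0.5)
  expect_equal(sum(half$a > 0), 1L)
  expect_equal(max(half$a), 4)
  expect_error_class(density_grid(point_cloud(rbind(c(0, 0, 0)), "LOCAL",
                                              e = 0), epsilon = -1),
                     "cottoncanopy_validation_error")
})

test_that("density matrix equals brute-force bin counting, conserving mass", {
  for (case in 1:20) {
    set.seed(300 + case)
    n <- sample(500:2000, 1)
    x <- runif(n, 0, sample(3:8, 1))
    e <- runif(n, 0, sample(1:3, 1))
    pc <- point_cloud(cbind(x, runif(n), rnorm(n)), "LOCAL", e = e)
    eps <- sample(c(0.25, 0.5, 1, 2), 1)
    grid <- density_grid(pc, epsilon = eps)
    expect_equal(sum(grid$a) * eps^2, n)  # exact integer identity
    counts <- oracle_bin_counts(x, e, min(x), min(e), eps,
                                nrow(grid$a), ncol(grid$a))
    expect_equal(grid$a, counts / eps^2)
  }
})

test_that("occupancy ratio counts cells at or above 0.2 of the mean", {
  pc <- point_cloud(cbind(runif(100, 0, 2), runif(100), 0), "LOCAL",
                    e = runif(100, 0, 2))
  # uniform nonzero grid -> 1
  u <- density_grid(point_cloud(cbind(rep(c(0.25, 0.75), 50),
                                      runif(100), 0), "LOCAL",
                                e = rep(c(0.25, 0.75), each = 50)),
                    epsilon = 0.5)
  if (all(u$a > 0)) expect_equal(occupancy_ratio(u), 1)

  # one occupied cell in a 10 x 10 grid -> exactly 0.01
  g <- density_grid(point_cloud(rbind(c(0.05, 0, 0)), "LOCAL", e = 0.05),
                    epsilon = 1,
                    extents = list(u = c(0, 10), v = c(0, 10)))
  expect_identical(dim(g$a), c(10L, 10L))
  expect_equal(occupancy_ratio(g), 0.01)

  # all-zero grid is degenerate: warned, returns 1 under the >= convention
  z <- g; z$a[] <- 0
  expect_warning(r <- occupancy_ratio(z), "degenerate")
  expect_equal(r, 1)

  # bounded in [0, 1] on fuzzed grids
  set.seed(31)
  for (i in 1:50) {
    gr <- density_grid(point_cloud(cbind(runif(200, 0, 5), runif(200), 0),
                                   "LOCAL", e = runif(200, 0, 2)),
                       epsilon = 0.5)
    r <- occupancy_ratio(gr)
    expect_gte(r, 0); expect_lte(r, 1)
  }
})

test_that("canopy diameter equals the all-pairs scan and is rigid-invariant", {
  expect_equal(canopy_diameter(rbind(c(0, 0, 1), c(3, 0, 1))), 3)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(canopy_diameter(sq), sqrt(2))
  expect_error_class(canopy_diameter(rbind(c(0, 0, 0))),
                     "cottoncanopy_validation_error")

  set.seed(33)
  m <- cbind(rnorm(200), rnorm(200), 0)
  d <- canopy_diameter(m)
  expect_equal(d, oracle_diameter(m[, 1:2]), tolerance = 1e-12)
  # never less than any sampled pair distance
  expect_gte(d, max(dist(m[sample(200, 50), 1:2])))
  # translation and rotation invariance
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  m2 <- cbind(m[, 1:2] %*% R + 5, 0)
  expect_equal(canopy_diameter(m2), d, tolerance = 1e-9)
  # region restriction matches the oracle on the member subset
  keep <- m[, 1] >= -1 & m[, 1] <= 1 & m[, 2] >= -1 & m[, 2] <= 1
  expect_equal(canopy_diameter(m, region = c(-1, -1, 1, 1)),
               oracle_diameter(m[keep, 1:2]), tolerance = 1e-12)
  # bounding-box alternative
  expect_gte(canopy_diameter(m, method = "bbox"), d)
})

test_that("quadrat features are bounded and respond to canopy density", {
  f <- small_field()
  can <- f$local[f$local$type != "ground" & f$local$e > 0.05, ]
  pc <- point_cloud(as.matrix(can[c("x", "y", "z")]), "LOCAL", e = can$e)
  feats <- quadrat_features(pc, f$layout)
  expect_identical(nrow(feats), nrow(f$layout$quadrats))
  expect_true(all(feats$g >= 0 & feats$g <= 1))
  expect_true(all(feats$d_t >= 0 & feats$d_t <= sqrt(2) + 1e-9))
  expect_true(all(feats$n_points > 0))
})
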