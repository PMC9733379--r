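test_that("DSM rasterization applies the per-cell maximum rule", {
  one <- rasterize_dsm(rbind(c(0.5, 0.5, 2.0)), cell_size = 1)
  expect_identical(dim(one$values), c(1L, 1L))
  expect_equal(one$values[1, 1], 2.0)

  two <- rasterize_dsm(rbind(c(0.2, 0.2, 1), c(0.3, 0.3, 3)), cell_size = 1)
  expect_equal(two$values[1, 1], 3)

  expect_error_class(rasterize_dsm(matrix(0, 0, 3)),
                     "cottoncanopy_validation_error")
  expect_error_class(rasterize_dsm(rbind(c(0, 0, 0)), cell_size = 0),
                     "cottoncanopy_validation_error")
})

test_that("every DSM cell equals the brute-force max over its members", {
  set.seed(21)
  m <- cbind(runif(4000, 0, 5), runif(4000, 0, 3), rnorm(4000))
  s <- 0.25
  dsm <- rasterize_dsm(m, cell_size = s, fill = "none")
  ix <- pmin(floor((m[, 1] - dsm$x0) / s) + 1, dsm$nx)
  iy <- pmin(floor((m[, 2] - dsm$y0) / s) + 1, dsm$ny)
  expect_equal(dsm$values, oracle_dsm_cell_max(m, dsm$nx, dsm$ny, ix, iy))
  # conservation: no value above the global max, none below the global min
  expect_lte(max(dsm$values, na.rm = TRUE), max(m[, 3]))
  expect_gte(min(dsm$values, na.rm = TRUE), min(m[, 3]))
})

test_that("empty cells are filled from nearby surface values", {
  set.seed(22)
  m <- cbind(runif(50, 0, 10), runif(50, 0, 10), runif(50, 1, 2))
  dsm <- rasterize_dsm(m, cell_size = 0.5)
  expect_false(anyNA(dsm$values))
  expect_true(all(dsm$values >= 1 & dsm$values <= 2))
  expect_identical(dsm$fill, "nearest")
  open <- rasterize_dsm(m, cell_size = 0.5, fill = "none")
  expect_gt(sum(is.na(open$values)), 0)
  # filled cells keep their original values
  keep <- !is.na(open$values)
  expect_equal(dsm$values[keep], open$values[keep])
})

test_that("percentile upper boundary follows the sorted-order formula", {
  m <- expand.grid(x = (1:10) - 0.5, y = (1:10) - 0.5)
  vals <- seq_len(100)
  dsm <- rasterize_dsm(cbind(m$x, m$y, vals), cell_size = 1)
  expect_equal(upper_boundary_p99(dsm, c(0, 0, 10, 10)), 99.01)
  expect_equal(upper_boundary_p99(dsm, c(0, 0, 10, 10), 50),
               oracle_percentile(vals, 50))
  # constant region: any percentile returns the constant
  flat <- rasterize_dsm(cbind(m$x, m$y, 1.7), cell_size = 1)
  for (p in c(10, 50, 95, 99))
    expect_equal(upper_boundary_p99(flat, c(0, 0, 10, 10), p), 1.7)
  # sub-region matches the oracle on its member set
  half <- upper_boundary_p99(dsm, c(0, 0, 5, 10), 99)
  members <- vals[rep(1:10, 10) <= 5]
  expect_equal(half, oracle_percentile(members, 99))
  # monotone in the percentile parameter
  ps <- c(5, 25, 50, 75, 90, 95, 99)
  ub <- vapply(ps, function(p) upper_boundary_p99(dsm, c(0, 0, 10, 10), p), 0)
  expect_true(all(diff(ub) > 0))
  expect_error_class(upper_boundary_p99(dsm, c(20, 20, 21, 21)),
                     "cottoncanopy_validation_error")
})

test_that("height estimation is the percentile minus plot ground", {
  f <- small_field()
  loc <- localize_cloud(f$cloud)
  dsm <- rasterize_dsm(loc, cell_size = 0.05)
  q <- f$layout$quadrats
  qt <- data.frame(quadrat_id = q$quadrat_id, plot_id = q$plot_id,
                   p99 = vapply(seq_len(nrow(q)), function(i)
                     upper_boundary_p99(dsm, c(q$xmin[i], q$ymin[i],
                                               q$xmax[i], q$ymax[i])), 0),
                   h_c = f$measurements$h_c)
  gm <- ground_from_samples(qt)
  he <- estimate_heights(dsm, gm, f$layout)
  expect_identical(nrow(he$plots), nrow(f$layout$plots))
  expect_identical(nrow(he$quadrats), nrow(f$layout$quadrats))
  expect_equal(he$plots$h_f, he$plots$p99 - he$plots$h_ground)
  expect_equal(he$quadrats$h_e, he$quadrats$p99 - he$quadrats$h_ground)

  # estimated quadrat heights track the measured tallest-plant heights
  rep_q <- metrics_report(f$measurements$h_c, he$quadrats$h_e)
  expect_lt(rep_q$rmse, 0.03)
  expect_gt(rep_q$r2_standard, 0.9)

  # missing plot ground elevation is caught
  gm2 <- gm; gm2$plots <- gm2$plots[-1, ]
  expect_error_class(estimate_heights(dsm, gm2, f$layout),
                     "cottoncanopy_validation_error")
})

test_that("height pipeline is equivariant to a constant elevation shift", {
  f <- small_field()
  loc <- localize_cloud(f$cloud)
  shift <- 3.21
  run_one <- function(coords) {
    dsm <- rasterize_dsm(coords, cell_size = 0.1)
    q <- f$layout$quadrats
    qt <- data.frame(quadrat_id = q$quadrat_id, plot_id = q$plot_id,
                     p99 = vapply(seq_len(nrow(q)), function(i)
                       upper_boundary_p99(dsm, c(q$xmin[i], q$ymin[i],
                                                 q$xmax[i], q$ymax[i])), 0),
                     h_c = f$measurements$h_c)
    estimate_heights(dsm, ground_from_samples(qt), f$layout)
  }
  base <- run_one(loc$coords)
  lifted <- run_one(loc$coords + cbind(0, 0, rep(shift, nrow(loc$coords))))
  expect_equal(lifted$plots$p99, base$plots$p99 + shift, tolerance = 1e-9)
  expect_equal(lifted$plots$h_f, base$plots$h_f, tolerance = 1e-9)
  expect_equal(lifted$quadrats$h_e, base$quadrats$h_e, tolerance = 1e-9)
})

test_that("an all-ground field estimates heights near zero", {
  set.seed(23)
  n <- 20000
  m <- cbind(runif(n, 0, 10), runif(n, 0, 10), rnorm(n, 0, 0.005))
  layout <- make_plot_layout(c(10, 10))
  dsm <- rasterize_dsm(m, cell_size = 0.1)
  q <- layout$quadrats
  qt <- data.frame(quadrat_id = q$quadrat_id, plot_id = q$plot_id,
                   p99 = vapply(seq_len(nrow(q)), function(i)
                     upper_boundary_p99(dsm, c(q$xmin[i], q$ymin[i],
                                               q$xmax[i], q$ymax[i])), 0),
                   h_c = 0)
  he <- estimate_heights(dsm, ground_from_samples(qt), layout)
  expect_lt(max(abs(he$plots$h_f)), 0.03)
})
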