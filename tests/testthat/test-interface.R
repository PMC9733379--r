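test_that("XYZ-CSV clouds survive a write/read round trip", {
  f <- small_field()
  path <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(f$cloud, path)
  back <- read_point_cloud(path)
  expect_identical(back$frame, "WGS84")
  expect_equal(back$coords, f$cloud$coords, tolerance = 1e-9)

  # local clouds carry their frame in the sidecar
  loc <- localize_cloud(f$cloud)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_point_cloud(loc, path2)
  back2 <- read_point_cloud(path2)
  expect_identical(back2$frame, "LOCAL")
  expect_s3_class(back2$local_frame, "local_frame")
  expect_equal(back2$local_frame$origin_geo, loc$local_frame$origin_geo)

  tiny <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("lat,lon,h", "1,2,3", "4,5,6", "7,8,9"), tiny)
  expect_identical(nrow(read_point_cloud(tiny)$coords), 3L)
})

test_that("PLY clouds round trip and malformed headers are rejected", {
  pc <- point_cloud(cbind(c(1.5, 2.5), c(0.25, 0.75), c(3, 4)), "LOCAL",
                    e = c(0.1, 0.2))
  path <- withr::local_tempfile(fileext = ".ply")
  write_point_cloud(pc, path)
  back <- read_point_cloud(path)
  expect_identical(back$frame, "LOCAL")
  expect_equal(back$coords, pc$coords, tolerance = 1e-9)
  expect_equal(back$e, pc$e, tolerance = 1e-9)

  bad <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 1",
               "property double a", "property double y", "property double z",
               "end_header", "1 2 3"), bad)
  expect_error_class(read_point_cloud(bad), "cottoncanopy_io_error")
  notply <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("not a ply"), notply)
  expect_error_class(read_point_cloud(notply), "cottoncanopy_io_error")
  # malformed body row reported with its line number
  short <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "comment frame LOCAL",
               "element vertex 2",
               "property double x", "property double y", "property double z",
               "end_header", "1 2 3", "4 5"), short)
  expect_error(read_point_cloud(short), "line")
})

test_that("layout GeoJSON round trips", {
  layout <- make_plot_layout(c(10, 10))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_layout(layout, path)
  back <- read_layout(path)
  expect_equal(back$plots[order(back$plots$plot_id), ],
               layout$plots[order(layout$plots$plot_id), ],
               ignore_attr = TRUE)
  expect_equal(back$quadrats[order(back$quadrats$quadrat_id), ],
               layout$quadrats[order(layout$quadrats$quadrat_id), ],
               ignore_attr = TRUE)
  # the file is genuine GeoJSON
  obj <- jsonlite::read_json(path)
  expect_identical(obj$type, "FeatureCollection")
  expect_identical(obj$features[[1]]$geometry$type, "Polygon")
})

test_that("run_pipeline produces a complete deterministic report", {
  f <- small_field()
  cfg <- pipeline_config(f$cloud, f$measurements, f$layout)
  rep1 <- run_pipeline(cfg)
  expect_s3_class(rep1, "run_report")
  expect_identical(nrow(rep1$heights$plots), nrow(f$layout$plots))
  expect_identical(nrow(rep1$lai), nrow(f$layout$quadrats))
  expect_false(anyNA(rep1$lai$lai_pred))
  expect_true(all(c("mae", "rmse", "r2_ratio", "r2_standard") %in%
                  names(rep1$metrics$height)))
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$heights, rep2$heights)
  expect_identical(rep1$lai, rep2$lai)
  expect_identical(rep1$provenance$config_hash, rep2$provenance$config_hash)
})

test_that("fit mode validates inputs before computing", {
  f <- small_field()
  meas <- f$measurements[setdiff(names(f$measurements), "lai")]
  cfg <- pipeline_config(f$cloud, meas, f$layout, mode = "fit")
  expect_error_class(run_pipeline(cfg), "cottoncanopy_validation_error")
  expect_error_class(pipeline_config(f$cloud, f$measurements, f$layout,
                                     cell_size = -1),
                     "cottoncanopy_validation_error")
})

test_that("pipeline results are invertible back to WGS84 provenance", {
  f <- small_field()
  rep <- run_pipeline(pipeline_config(f$cloud, f$measurements, f$layout,
                                      out_dir = withr::local_tempdir()))
  expect_true(all(c("config_hash", "seed", "n_points") %in%
                  names(rep$provenance)))
})

test_that("CLI subcommands chained through files match run_pipeline", {
  dir <- withr::local_tempdir()
  sim <- file.path(dir, "sim")
  expect_identical(suppressMessages(cli_main(c(
    "simulate", "--out-dir", sim, "--seed", "7",
    "--extent-x", "10", "--extent-y", "10",
    "--points-per-plant", "120", "--ground-density", "120"))), 0L)
  expect_true(file.exists(file.path(sim, "cloud.csv")))
  expect_true(file.exists(file.path(sim, "layout.geojson")))

  out <- file.path(dir, "run")
  expect_identical(suppressMessages(cli_main(c(
    "run", "--cloud", file.path(sim, "cloud.csv"),
    "--measurements", file.path(sim, "measurements.csv"),
    "--layout", file.path(sim, "layout.geojson"),
    "--out-dir", out))), 0L)
  report <- jsonlite::read_json(file.path(out, "report.json"),
                                simplifyVector = TRUE)

  # the same analysis in memory gives the same metrics
  f <- small_field(seed = 7)
  rep <- run_pipeline(pipeline_config(f$cloud, f$measurements, f$layout))
  expect_equal(report$metrics$height$rmse, rep$metrics$height$rmse,
               tolerance = 1e-6)
  expect_equal(report$metrics$lai$mae, rep$metrics$lai$mae, tolerance = 1e-6)

  # individual stage subcommand agrees with the full run
  gfile <- file.path(dir, "ground.csv")
  expect_identical(suppressMessages(cli_main(c(
    "ground", "--cloud", file.path(sim, "cloud.csv"),
    "--measurements", file.path(sim, "measurements.csv"),
    "--layout", file.path(sim, "layout.geojson"), "--out", gfile))), 0L)
  gtab <- read.csv(gfile)
  expect_equal(gtab$h_gf, rep$ground$plots$h_gf, tolerance = 1e-6)
})

test_that("CLI rejects malformed invocations without crashing", {
  expect_identical(suppressMessages(cli_main(c("nonsense", "--x", "1"))), 1L)
  expect_identical(suppressMessages(cli_main(c("simulate"))), 1L)
  expect_output(cli_main(character(0)), "usage")
})
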