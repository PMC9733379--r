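## End-to-end analysis: localize -> ground model -> DSM heights -> density
## and diameter descriptors -> LAI prediction or fitting -> metrics.

#' Pipeline configuration
#'
#' Inputs may be in-memory objects (a `point_cloud`, data frames, a
#' `plot_layout`) or file paths (XYZ-CSV/PLY cloud, measurements CSV,
#' layout GeoJSON).
#'
#' @param cloud `point_cloud` (WGS84 or LOCAL) or a file path.
#' @param measurements Measurements data frame or CSV path (quadrat bounds,
#'   `h_c`, optional `lai`).
#' @param layout `plot_layout` or GeoJSON path.
#' @param cell_size DSM cell size (m).
#' @param percentile Canopy upper-boundary percentile.
#' @param epsilon Field-level density-grid cell size (m).
#' @param feature_epsilon Per-quadrat density-grid cell size for `g` (m).
#' @param axes Density-grid axes spec.
#' @param canopy_threshold Relative-height cutoff (m) for canopy
#'   segmentation; 0.05 by default to buffer ground-point and terrain-model
#'   noise.
#' @param ground_mode `"inverted"` or `"as-printed"` (see
#'   [ground_from_samples()]).
#' @param mode `"predict"` applies `model`; `"fit"` fits a new model by
#'   stepwise least squares on the measured `lai` column.
#' @param model `lai_model` used in predict mode (default the published one).
#' @param row_spacing Row-spacing divisor for fitting (m).
#' @param criterion Stepwise selection criterion for fit mode.
#' @param seed Integer seed (recorded; the pipeline itself is deterministic).
#' @param out_dir Optional directory; when set, intermediates and the report
#'   are persisted there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cloud, measurements, layout,
                            cell_size = 0.05, percentile = 99,
                            epsilon = 1, feature_epsilon = 0.2, axes = "xe",
                            canopy_threshold = 0.05,
                            ground_mode = c("inverted", "as-printed"),
                            mode = c("predict", "fit"),
                            model = published_lai_model(),
                            row_spacing = 0.76,
                            criterion = "BIC",
                            seed = 1L, out_dir = NULL) {
  cfg <- list(cloud = cloud, measurements = measurements, layout = layout,
              cell_size = cell_size, percentile = percentile,
              epsilon = epsilon, feature_epsilon = feature_epsilon,
              axes = axes, canopy_threshold = canopy_threshold,
              ground_mode = match.arg(ground_mode),
              mode = match.arg(mode), model = model,
              row_spacing = row_spacing, criterion = criterion,
              seed = as.integer(seed), out_dir = out_dir)
  if (cfg$cell_size <= 0 || cfg$epsilon <= 0 || cfg$feature_epsilon <= 0)
    stop_validation("cell sizes must be positive")
  if (cfg$percentile <= 0 || cfg$percentile > 100)
    stop_validation("percentile must be in (0, 100]")
  structure(cfg, class = "pipeline_config")
}

resolve_cloud <- function(x) {
  if (inherits(x, "point_cloud")) x
  else if (is.character(x)) read_point_cloud(x)
  else stop_validation("cloud must be a point_cloud or a file path")
}

resolve_layout <- function(x) {
  if (inherits(x, "plot_layout")) x
  else if (is.character(x)) read_layout(x)
  else stop_validation("layout must be a plot_layout or a GeoJSON path")
}

resolve_measurements <- function(x) {
  if (is.data.frame(x)) x
  else if (is.character(x)) read_measurements(x)
  else stop_validation("measurements must be a data frame or a CSV path")
}

#' Run the full canopy-height and LAI analysis
#'
#' Stages: localize the cloud (WGS84 to east-north-up), rasterize the DSM,
#' take per-quadrat percentile upper boundaries, invert ground elevations
#' from the measured tallest-plant heights, estimate plot and quadrat
#' heights, fit a ground plane to the inverted quadrat ground points to
#' attach per-point relative heights, segment the canopy, compute the
#' per-quadrat occupancy and diameter descriptors, then predict LAI with
#' the configured model (or fit a new one), and evaluate both height and
#' LAI estimates against the measurements.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report`: height and feature tables, the LAI table, the
#'   metrics block, the LAI model used, and provenance (config hash, seed).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  measurements <- resolve_measurements(config$measurements)
  layout <- resolve_layout(config$layout)
  if (config$mode == "fit" && !"lai" %in% names(measurements))
    stop_validation("fit mode requires a measured 'lai' column")

  cloud <- resolve_cloud(config$cloud)
  local <- if (cloud$frame == "WGS84") localize_cloud(cloud) else cloud

  dsm <- rasterize_dsm(local, cell_size = config$cell_size)

  ## ground inversion from sampled heights + quadrat DSM percentiles
  q <- layout$quadrats
  p99_i <- vapply(seq_len(nrow(q)), function(i)
    upper_boundary_p99(dsm, c(q$xmin[i], q$ymin[i], q$xmax[i], q$ymax[i]),
                       config$percentile), 0)
  qt <- data.frame(quadrat_id = q$quadrat_id, plot_id = q$plot_id,
                   p99 = p99_i,
                   h_c = measurements$h_c[match(q$quadrat_id,
                                                measurements$quadrat_id)],
                   stringsAsFactors = FALSE)
  ground <- ground_from_samples(qt, mode = config$ground_mode)

  heights <- estimate_heights(dsm, ground, layout, config$percentile)

  ## terrain plane through the inverted quadrat ground points -> per-point e
  qc <- cbind((q$xmin + q$xmax) / 2, (q$ymin + q$ymax) / 2,
              ground$quadrats$h_g[match(q$quadrat_id,
                                        ground$quadrats$quadrat_id)])
  plane <- fit_plane_orthogonal(qc)
  local <- relative_heights(local, plane)
  canopy <- segment_above_ground(local, threshold = config$canopy_threshold)

  feats <- quadrat_features(canopy, layout, epsilon = config$feature_epsilon,
                            axes = config$axes)
  feats$h_e <- heights$quadrats$h_e[match(feats$quadrat_id,
                                          heights$quadrats$quadrat_id)]
  if ("lai" %in% names(measurements))
    feats$lai <- measurements$lai[match(feats$quadrat_id,
                                        measurements$quadrat_id)]

  field_density <- density_grid(canopy, epsilon = config$epsilon,
                                axes = config$axes)

  model <- if (config$mode == "fit") {
    fit_lai_stepwise(feats, candidates = c("g", "d_t", "h_e"),
                     row_spacing = config$row_spacing,
                     criterion = config$criterion)
  } else config$model
  lai_pred <- predict_lai(model, feats)
  lai_tab <- data.frame(quadrat_id = feats$quadrat_id,
                        plot_id = feats$plot_id,
                        lai_pred = lai_pred,
                        lai_measured = if ("lai" %in% names(feats)) feats$lai
                                       else NA_real_,
                        stringsAsFactors = FALSE)

  metrics <- list(
    height = metrics_report(
      measurements$h_c[match(heights$quadrats$quadrat_id,
                             measurements$quadrat_id)],
      heights$quadrats$h_e))
  if ("lai" %in% names(feats) && !anyNA(feats$lai))
    metrics$lai <- metrics_report(lai_tab$lai_measured, lai_tab$lai_pred)

  report <- structure(list(
    heights = heights, features = feats, lai = lai_tab,
    field_density = field_density, ground = ground, model = model,
    metrics = metrics,
    provenance = list(
      config_hash = config_hash(list(
        options = config[setdiff(names(config),
                                 c("out_dir", "cloud", "measurements",
                                   "layout", "model"))],
        n_points = nrow(local$coords),
        coord_sum = sum(local$coords))),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("cottoncanopy")),
      n_points = nrow(local$coords))),
    class = "run_report")

  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (%d points, config %s)\n",
              x$provenance$n_points, x$provenance$config_hash))
  cat(sprintf("  plots: %d, quadrats: %d\n", nrow(x$heights$plots),
              nrow(x$heights$quadrats)))
  cat("  height metrics:\n"); print(x$metrics$height)
  if (!is.null(x$metrics$lai)) { cat("  LAI metrics:\n"); print(x$metrics$lai) }
  invisible(x)
}

persist_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- report$provenance$config_hash
  wcsv <- function(df, name) {
    df$config_hash <- h
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(report$heights$plots, "plot_heights.csv")
  wcsv(report$heights$quadrats, "quadrat_heights.csv")
  wcsv(report$features, "features.csv")
  wcsv(report$lai, "lai.csv")
  wcsv(report$ground$plots, "ground.csv")
  utils::write.csv(report$field_density$a,
                   file.path(out_dir, "density_matrix.csv"), row.names = FALSE)
  write_lai_model(report$model, file.path(out_dir, "lai_model.json"))
  jsonlite::write_json(
    list(metrics = report$metrics, provenance = report$provenance),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(out_dir)
}
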