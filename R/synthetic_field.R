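## Synthetic cotton-field generator. Emulates the surveyed trial: a
## 40 x 20 m field on a gently sloped terrain plane, cotton rows at 0.60 m
## spacing, 32 plots of 5 x 5 m with four 1 x 1 m sampling quadrats each,
## per-plant canopy point blobs whose leaf-point count shrinks with a
## defoliation-stage parameter, and quadrat LAI values drawn from a known
## linear model of the canopy descriptors. Every output is deterministic
## given (config, seed), and ground truth is recorded for each stage of the
## pipeline.

#' Configuration of a synthetic cotton field
#'
#' Defaults restate the surveyed trial: 40 x 20 m extent, 0.60 m row
#' spacing, mean plant height 0.60 m (sd 0.05), 32 plots / 128 quadrats,
#' and the published LAI model as the generating truth. Point and
#' measurement noise default to 0.005 m (RTK-grade); LAI measurement noise
#' defaults to 0.1.
#'
#' @param extent Field size `c(x, y)` in metres.
#' @param origin Geodetic origin `c(lat, lon, h)` the local field frame is
#'   anchored at when exporting WGS84 coordinates.
#' @param base_elev Ground elevation at the field corner (m, local frame).
#' @param slope Terrain plane slope `c(sx, sy)` in m/m.
#' @param row_spacing Distance between plant rows (m); rows run along x.
#' @param plant_spacing In-row plant spacing (m).
#' @param height_mean,height_sd Plant height distribution (m): within-plot
#'   plant-to-plant sd.
#' @param height_plot_sd Between-plot height sd (m); emulates the smooth
#'   fertility/vigor gradients that spread measured heights across a real
#'   field.
#' @param canopy_radius Horizontal canopy dome radius (m).
#' @param dome_drop Fractional height drop from dome centre to edge.
#' @param surface_depth Mean depth (m) of points below the canopy surface;
#'   photogrammetric clouds sample the visible surface densely and the
#'   canopy interior sparsely.
#' @param points_per_plant Expected leaf points per plant at stage 0.
#' @param vigor_sd Log-sd of per-plant vigor (scales leaf-point count).
#' @param stem_points Stem points per plant (retained under defoliation).
#' @param ground_density Ground points per square metre.
#' @param point_noise_sd Per-point elevation noise sd (m).
#' @param canopy_threshold Relative-height cutoff (m) defining the canopy
#'   subset used for the true descriptors; matches the pipeline default.
#' @param stage Defoliation stage in [0, 1]: fraction of leaf points removed.
#' @param sd_height Measurement noise sd on quadrat tallest-plant height (m).
#' @param sd_lai Measurement noise sd on quadrat LAI.
#' @param lai_truth List `t` (named coefficients for `g`, `d_t`, `h_e`),
#'   `j` (intercept), `delta` (row-spacing divisor): the generating model.
#' @param feature_epsilon Density-grid cell size (m) used for the
#'   per-quadrat occupancy descriptor `g`.
#' @param seed Integer seed; the generator never touches global RNG state.
#' @return A validated `field_config` list.
#' @export
field_config <- function(extent = c(40, 20),
                         origin = c(lat = 37.947351231, lon = 117.835755425,
                                    h = 4.1627),
                         base_elev = 0.5,
                         slope = c(0.004, 0.002),
                         row_spacing = 0.60,
                         plant_spacing = 0.30,
                         height_mean = 0.60, height_sd = 0.05,
                         height_plot_sd = 0.08,
                         canopy_radius = 0.25,
                         dome_drop = 0.4,
                         surface_depth = 0.04,
                         points_per_plant = 400,
                         vigor_sd = 0.3,
                         stem_points = 30,
                         ground_density = 250,
                         point_noise_sd = 0.005,
                         canopy_threshold = 0.05,
                         stage = 0,
                         sd_height = 0.005,
                         sd_lai = 0.1,
                         lai_truth = list(
                           t = c(g = 1.37618, d_t = 0.66738, h_e = -0.02035),
                           j = -0.51087, delta = 0.76),
                         feature_epsilon = 0.2,
                         seed = 1L) {
  cfg <- list(extent = extent, origin = origin, base_elev = base_elev,
              slope = slope, row_spacing = row_spacing,
              plant_spacing = plant_spacing, height_mean = height_mean,
              height_sd = height_sd, height_plot_sd = height_plot_sd,
              canopy_radius = canopy_radius, dome_drop = dome_drop,
              surface_depth = surface_depth,
              points_per_plant = points_per_plant, vigor_sd = vigor_sd,
              stem_points = stem_points, ground_density = ground_density,
              point_noise_sd = point_noise_sd,
              canopy_threshold = canopy_threshold, stage = stage,
              sd_height = sd_height, sd_lai = sd_lai, lai_truth = lai_truth,
              feature_epsilon = feature_epsilon, seed = as.integer(seed))
  with(cfg, {
    if (any(extent <= 0)) stop_validation("field extent must be positive")
    if (row_spacing <= 0 || plant_spacing <= 0)
      stop_validation("plant/row spacings must be positive")
    if (ground_density <= 0 || points_per_plant <= 0)
      stop_validation("point densities must be positive")
    if (stage < 0 || stage > 1)
      stop_validation("defoliation stage must lie in [0, 1]")
    if (!all(c("t", "j", "delta") %in% names(lai_truth)) ||
        lai_truth$delta <= 0)
      stop_validation("lai_truth needs elements t, j and delta > 0")
  })
  structure(cfg, class = "field_config")
}

#' Tile a field extent into plots and sampling quadrats
#'
#' Tiles the extent into square plots (5 x 5 m by default) and places four
#' non-overlapping 1 x 1 m quadrats per plot at deterministic offsets near
#' the plot quarter points. A 40 x 20 m extent yields 32 plots and 128
#' quadrats.
#'
#' @param extent Field size `c(x, y)` (m); must fit at least one plot.
#' @param plot_size Plot edge length (m).
#' @param quadrat_size Quadrat edge length (m).
#' @return A [plot_layout()].
#' @export
make_plot_layout <- function(extent = c(40, 20), plot_size = 5,
                             quadrat_size = 1) {
  npx <- floor(extent[1] / plot_size); npy <- floor(extent[2] / plot_size)
  if (npx < 1 || npy < 1)
    stop_validation("extent %g x %g m cannot fit a %g m plot",
                    extent[1], extent[2], plot_size)
  grid <- expand.grid(ix = seq_len(npx) - 1L, iy = seq_len(npy) - 1L)
  plots <- data.frame(
    plot_id = sprintf("P%02d", seq_len(nrow(grid))),
    xmin = grid$ix * plot_size, ymin = grid$iy * plot_size,
    stringsAsFactors = FALSE)
  plots$xmax <- plots$xmin + plot_size
  plots$ymax <- plots$ymin + plot_size
  # quadrat lower-left offsets within a plot: around the quarter points
  q <- plot_size / 4 - quadrat_size / 2
  q2 <- 3 * plot_size / 4 - quadrat_size / 2
  offs <- rbind(c(q, q), c(q2, q), c(q, q2), c(q2, q2))
  quadrats <- do.call(rbind, lapply(seq_len(nrow(plots)), function(i) {
    data.frame(quadrat_id = sprintf("%sQ%d", plots$plot_id[i], 1:4),
               plot_id = plots$plot_id[i],
               xmin = plots$xmin[i] + offs[, 1],
               ymin = plots$ymin[i] + offs[, 2],
               stringsAsFactors = FALSE)
  }))
  quadrats$xmax <- quadrats$xmin + quadrat_size
  quadrats$ymax <- quadrats$ymin + quadrat_size
  plot_layout(plots, quadrats)
}

# Terrain plane elevation of a config at local (x, y).
ground_elev_at <- function(config, x, y) {
  config$base_elev + config$slope[1] * x + config$slope[2] * y
}

#' Generate a synthetic cotton-field point cloud with ground truth
#'
#' Builds the local-frame cloud (sloped ground points, per-plant leaf blobs
#' and stems, leaf count scaled by `1 - stage`), converts it to WGS84
#' through the real inverse geodetic transform, and emits quadrat
#' measurements: tallest-plant height (truth plus noise) and LAI drawn from
#' the configured linear model of the true canopy descriptors plus noise.
#'
#' @param config A [field_config()].
#' @return List with elements:
#'   \describe{
#'     \item{cloud}{`point_cloud` in WGS84, carrying the generating frame.}
#'     \item{local}{data frame of generator-frame x, y, z, true relative
#'       height `e`, and point `type` (ground/leaf/stem).}
#'     \item{layout}{the [plot_layout()].}
#'     \item{measurements}{per-quadrat CSV-ready table: bounds, `h_c`, `lai`.}
#'     \item{truth}{per-quadrat and per-plot ground truth (descriptors,
#'       tallest heights, ground elevations) and the generating LAI model.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_field <- function(config) {
  stopifnot(inherits(config, "field_config"))
  layout <- make_plot_layout(config$extent)
  out <- with_seed(config$seed, generate_field_impl(config, layout))
  out
}

generate_field_impl <- function(config, layout) {
  ex <- config$extent[1]; ey <- config$extent[2]

  ## ground points
  n_ground <- round(config$ground_density * ex * ey)
  gx <- runif(n_ground, 0, ex); gy <- runif(n_ground, 0, ey)
  gz <- ground_elev_at(config, gx, gy) + rnorm(n_ground, 0, config$point_noise_sd)

  ## plant grid with jitter
  row_y <- seq(config$row_spacing / 2, ey - 1e-9, by = config$row_spacing)
  col_x <- seq(config$plant_spacing / 2, ex - 1e-9, by = config$plant_spacing)
  px <- rep(col_x, times = length(row_y)) + rnorm(length(col_x) * length(row_y), 0, 0.02)
  py <- rep(row_y, each = length(col_x)) + rnorm(length(col_x) * length(row_y), 0, 0.02)
  px <- pmin(pmax(px, 0), ex); py <- pmin(pmax(py, 0), ey)
  n_plants <- length(px)
  ## plant height = between-plot (spatial fertility) effect + individual
  layout_here <- make_plot_layout(config$extent)
  plot_of_plant <- canopy_plot(px, py, layout_here)
  plot_eff <- rnorm(nrow(layout_here$plots), 0, config$height_plot_sd)
  names(plot_eff) <- layout_here$plots$plot_id
  eff <- ifelse(is.na(plot_of_plant), 0, plot_eff[plot_of_plant])
  h_plant <- pmax(config$height_mean + eff +
                    rnorm(n_plants, 0, config$height_sd), 0.1)
  vigor <- exp(rnorm(n_plants, 0, config$vigor_sd))
  n_leaf <- pmax(rpois(n_plants, config$points_per_plant * vigor), 1L)

  ## leaf points: a photogrammetric cloud samples the visible canopy
  ## surface; model each plant as a dome z = h (1 - drop (r/R)^2) with
  ## points at exponentially distributed depth below the surface
  pid <- rep.int(seq_len(n_plants), n_leaf)
  total_leaf <- length(pid)
  ## defoliation shrinks the leafy extent as well as the point count
  R <- config$canopy_radius * (1 - 0.4 * config$stage)
  r <- R * sqrt(runif(total_leaf))
  th <- runif(total_leaf, 0, 2 * pi)
  surf <- h_plant[pid] * (1 - config$dome_drop * (r / R)^2)
  lz_rel <- pmax(surf - rexp(total_leaf, 1 / config$surface_depth), 0.02)
  lx <- px[pid] + r * cos(th)
  ly <- py[pid] + r * sin(th)
  lx <- pmin(pmax(lx, 0), ex); ly <- pmin(pmax(ly, 0), ey)

  ## stems (vertical lines; survive defoliation)
  ns <- config$stem_points
  sid <- rep(seq_len(n_plants), each = ns)
  sz_rel <- as.vector(vapply(h_plant, function(h) seq(0, h, length.out = ns),
                             numeric(ns)))
  sx <- px[sid] + rnorm(length(sid), 0, 0.01)
  sy <- py[sid] + rnorm(length(sid), 0, 0.01)
  sx <- pmin(pmax(sx, 0), ex); sy <- pmin(pmax(sy, 0), ey)

  ## elevation noise, then a single defoliation thinning pass at the end so
  ## the kept leaf set is nested across stages for a fixed seed
  lz <- ground_elev_at(config, lx, ly) + lz_rel + rnorm(total_leaf, 0, config$point_noise_sd)
  sz <- ground_elev_at(config, sx, sy) + sz_rel + rnorm(length(sid), 0, config$point_noise_sd)
  keep <- runif(total_leaf) < (1 - config$stage)

  local <- data.frame(
    x = c(gx, lx[keep], sx), y = c(gy, ly[keep], sy), z = c(gz, lz[keep], sz),
    type = rep(c("ground", "leaf", "stem"),
               c(n_ground, sum(keep), length(sid))),
    stringsAsFactors = FALSE)
  local$e <- local$z - ground_elev_at(config, local$x, local$y)

  ## ground truth ------------------------------------------------------------
  ## descriptors use the same operational canopy definition as the pipeline:
  ## plant points above the segmentation buffer, binned on true e
  canopy <- local[local$type != "ground", , drop = FALSE]
  canopy_feat <- canopy[canopy$e > config$canopy_threshold, , drop = FALSE]
  canopy_pc <- point_cloud(as.matrix(canopy_feat[c("x", "y", "z")]), "LOCAL",
                           e = canopy_feat$e)
  feats <- quadrat_features(canopy_pc, layout, epsilon = config$feature_epsilon)
  qn <- nrow(layout$quadrats)
  tallest_q <- vapply(seq_len(qn), function(i) {
    b <- layout$quadrats[i, ]
    inq <- canopy$x >= b$xmin & canopy$x <= b$xmax &
           canopy$y >= b$ymin & canopy$y <= b$ymax
    if (!any(inq)) 0 else max(canopy$e[inq])
  }, 0)
  pn <- nrow(layout$plots)
  plot_idx <- match(canopy_plot(canopy$x, canopy$y, layout), layout$plots$plot_id)
  tallest_p <- vapply(seq_len(pn), function(i) {
    inp <- which(plot_idx == i)
    if (!length(inp)) 0 else max(canopy$e[inp])
  }, 0)
  ground_p <- ground_elev_at(config,
                             (layout$plots$xmin + layout$plots$xmax) / 2,
                             (layout$plots$ymin + layout$plots$ymax) / 2)

  tq <- config$lai_truth$t
  lai_true <- (tq[["g"]] * feats$g + tq[["d_t"]] * feats$d_t +
               tq[["h_e"]] * tallest_q + config$lai_truth$j) / config$lai_truth$delta

  measurements <- data.frame(
    quadrat_id = layout$quadrats$quadrat_id,
    plot_id = layout$quadrats$plot_id,
    xmin = layout$quadrats$xmin, ymin = layout$quadrats$ymin,
    xmax = layout$quadrats$xmax, ymax = layout$quadrats$ymax,
    h_c = tallest_q + rnorm(qn, 0, config$sd_height),
    lai = lai_true + rnorm(qn, 0, config$sd_lai),
    stringsAsFactors = FALSE)

  truth <- list(
    quadrats = data.frame(quadrat_id = layout$quadrats$quadrat_id,
                          plot_id = layout$quadrats$plot_id,
                          g = feats$g, d_t = feats$d_t, h = tallest_q,
                          lai_true = lai_true, stringsAsFactors = FALSE),
    plots = data.frame(plot_id = layout$plots$plot_id,
                       ground_elev = ground_p, tallest = tallest_p,
                       stringsAsFactors = FALSE),
    lai_model = config$lai_truth,
    n_leaf_total = total_leaf, n_leaf_kept = sum(keep),
    z_min = min(local$z))

  ## WGS84 export through the real inverse transform
  frame <- local_frame(config$origin[["lat"]], config$origin[["lon"]],
                       config$origin[["h"]])
  geo <- ecef_to_wgs84(from_local(frame, as.matrix(local[c("x", "y", "z")])))
  cloud <- point_cloud(geo, "WGS84", local_frame = frame)

  list(cloud = cloud, local = local, layout = layout,
       measurements = measurements, truth = truth, config = config)
}

# Map points to plot ids (NA outside every plot).
canopy_plot <- function(x, y, layout) {
  p <- layout$plots
  id <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(p))) {
    inp <- x >= p$xmin[i] & x < p$xmax[i] & y >= p$ymin[i] & y < p$ymax[i]
    id[inp] <- p$plot_id[i]
  }
  id
}
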