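## Ground-elevation modelling. Two routes are provided, mirroring field
## practice when no bare-earth DTM exists:
##   1. orthogonal-distance plane fits on low corridors between adjacent
##      sampling regions, giving per-point relative heights e;
##   2. inversion of measured tallest-plant heights against per-quadrat DSM
##      percentiles, giving per-plot ground elevations h_gf.

#' Orthogonal-distance plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances,
#' normalized by the squared normal length. The optimum is the plane through
#' the centroid whose normal is the principal direction of smallest variance
#' of the centered scatter; solved here by SVD. The normal is unit length
#' with its vertical component forced non-negative, so relative heights are
#' positive above ground.
#'
#' @param points n x 3 matrix of (x, y, z) in metres, n >= 3, non-collinear.
#' @return A `terrain_plane`: `normal` (o, p, q), `centroid`, and `objective`
#'   (the minimized sum of squared orthogonal distances).
#' @export
fit_plane_orthogonal <- function(points) {
  m <- as_xyz_matrix(points, "plane points")
  if (nrow(m) < 3)
    stop_degenerate("plane fit needs at least 3 points, got %d", nrow(m))
  ctr <- colMeans(m)
  centered <- sweep(m, 2, ctr)
  sv <- svd(centered, nu = 0)
  # collinear (or coincident) points leave the plane orientation undetermined
  if (sv$d[2] < max(sv$d[1], 1) * 1e-10)
    stop_degenerate("points are collinear; plane orientation is undetermined")
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  if (normal[3] < 0) normal <- -normal
  if (normal[3] == 0) {  # vertical plane: fix sign deterministically
    nz <- which(normal != 0)[1]
    if (normal[nz] < 0) normal <- -normal
  }
  structure(list(normal = c(o = normal[1], p = normal[2], q = normal[3]),
                 centroid = c(x = ctr[1], y = ctr[2], z = ctr[3]),
                 objective = sv$d[3]^2),
            class = "terrain_plane")
}

#' @export
print.terrain_plane <- function(x, ...) {
  cat(sprintf("terrain_plane: normal (%.5f, %.5f, %.5f), centroid z %.4f m\n",
              x$normal[1], x$normal[2], x$normal[3], x$centroid[3]))
  invisible(x)
}

# Elevation of the plane surface at horizontal positions (x, y).
plane_height_at <- function(plane, x, y) {
  n <- plane$normal; c0 <- plane$centroid
  if (n[["q"]] == 0) stop_degenerate("vertical plane has no height function")
  c0[["z"]] - (n[["o"]] * (x - c0[["x"]]) + n[["p"]] * (y - c0[["y"]])) / n[["q"]]
}

#' A 1 x 1 m sampling quadrat with its member points
#'
#' @param id Quadrat identifier.
#' @param bounds Numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param points n x 3 matrix of member points (local frame).
#' @param h_c Optional measured tallest-plant height in the quadrat (m).
#' @return A `sample_region` object.
#' @export
sample_region <- function(id, bounds, points, h_c = NA_real_) {
  bounds <- as.numeric(bounds)
  if (length(bounds) != 4 || bounds[1] >= bounds[3] || bounds[2] >= bounds[4])
    stop_validation("bounds must be c(xmin, ymin, xmax, ymax) with min < max")
  m <- as_xyz_matrix(points, "region points")
  inside <- m[, 1] >= bounds[1] & m[, 1] <= bounds[3] &
            m[, 2] >= bounds[2] & m[, 2] <= bounds[4]
  if (!all(inside))
    stop_validation("region %s: %d member points fall outside its bounds",
                    id, sum(!inside))
  structure(list(id = id, bounds = bounds, points = m, h_c = h_c),
            class = "sample_region")
}

#' Pick the lower of two adjacent sampling regions
#'
#' Compares the member-point centroids; the region whose centroid has the
#' lower elevation stands in for local bare ground. Ties go to the first
#' argument, deterministically.
#'
#' @param a,b `sample_region` objects with at least one member point each.
#' @return One of `a`, `b`.
#' @export
lowest_region <- function(a, b) {
  stopifnot(inherits(a, "sample_region"), inherits(b, "sample_region"))
  if (nrow(a$points) == 0 || nrow(b$points) == 0)
    stop_validation("lowest_region: both regions must contain points")
  if (mean(b$points[, 3]) < mean(a$points[, 3])) b else a
}

#' Terrain planes over corridors between adjacent sampling regions
#'
#' Regions are ordered along the field's long axis (x, by centre), consecutive
#' regions are paired, and for each pair the plane is fitted on the lower
#' region's points and assigned to the corridor spanning both regions'
#' bounds.
#'
#' @param regions List of `sample_region` objects (one row of plots).
#' @return List of elements `plane` (a `terrain_plane`) and `extent`
#'   (xmin, ymin, xmax, ymax of the corridor).
#' @export
fit_terrain_corridors <- function(regions) {
  stopifnot(length(regions) >= 2,
            all(vapply(regions, inherits, TRUE, "sample_region")))
  centers <- vapply(regions, function(r) (r$bounds[1] + r$bounds[3]) / 2, 0)
  regions <- regions[order(centers)]
  out <- vector("list", length(regions) - 1L)
  for (k in seq_len(length(regions) - 1L)) {
    a <- regions[[k]]; b <- regions[[k + 1L]]
    low <- lowest_region(a, b)
    out[[k]] <- list(
      plane = fit_plane_orthogonal(low$points),
      extent = c(min(a$bounds[1], b$bounds[1]), min(a$bounds[2], b$bounds[2]),
                 max(a$bounds[3], b$bounds[3]), max(a$bounds[4], b$bounds[4])))
  }
  out
}

#' Per-point relative heights above a terrain plane
#'
#' Computes the vertical (not orthogonal) offset of each point from the plane
#' surface evaluated at the point's horizontal position:
#' \eqn{e_i = z_i + q^{-1}(o (x_i - \bar x) + p (y_i - \bar y)) - \bar z}.
#'
#' @param cloud `point_cloud` in the LOCAL frame, or an n x 3 matrix.
#' @param plane A `terrain_plane` with non-zero vertical normal component.
#' @return If given a `point_cloud`, the same cloud with `e` attached;
#'   otherwise the numeric vector of relative heights.
#' @export
relative_heights <- function(cloud, plane) {
  stopifnot(inherits(plane, "terrain_plane"))
  n <- plane$normal
  if (n[["q"]] == 0)
    stop_degenerate("vertical terrain plane: relative height undefined")
  m <- cloud_coords(cloud, if (inherits(cloud, "point_cloud")) "LOCAL" else NULL)
  c0 <- plane$centroid
  e <- m[, 3] + (n[["o"]] * (m[, 1] - c0[["x"]]) +
                 n[["p"]] * (m[, 2] - c0[["y"]])) / n[["q"]] - c0[["z"]]
  if (inherits(cloud, "point_cloud")) {
    cloud$e <- unname(e)
    cloud
  } else unname(e)
}

#' Ground elevations inverted from sampled heights and DSM percentiles
#'
#' In each plot the four quadrats carry a measured tallest-plant height
#' `h_c` and a DSM upper boundary `p99`. The default `"inverted"` mode
#' reverse-solves the quadrat ground elevation as `h_g = p99 - h_c` and
#' averages the four values into the plot ground elevation `h_gf`. The
#' `"as-printed"` mode instead averages the four `p99` values directly;
#' it is kept only to reproduce that literal formula and is not a ground
#' elevation in any physical sense.
#'
#' @param quadrat_table Data frame with columns `quadrat_id`, `plot_id`,
#'   `p99` and `h_c` (metres).
#' @param mode `"inverted"` (default) or `"as-printed"`.
#' @return A `ground_model`: `$plots` (plot_id, h_gf) and `$quadrats`
#'   (quadrat_id, plot_id, h_g).
#' @export
ground_from_samples <- function(quadrat_table, mode = c("inverted", "as-printed")) {
  mode <- match.arg(mode)
  need <- c("quadrat_id", "plot_id", "p99", "h_c")
  miss <- setdiff(need, names(quadrat_table))
  if (length(miss))
    stop_validation("quadrat table missing column(s): %s", paste(miss, collapse = ", "))
  bad <- unique(quadrat_table$plot_id[!is.finite(quadrat_table$p99) |
                                      (mode == "inverted" & !is.finite(quadrat_table$h_c))])
  if (length(bad))
    stop_validation("missing quadrat measurements in plot(s): %s",
                    paste(bad, collapse = ", "))
  counts <- table(quadrat_table$plot_id)
  if (any(counts != 4))
    stop_validation("every plot needs exactly 4 quadrats; offending plot(s): %s",
                    paste(names(counts)[counts != 4], collapse = ", "))
  h_g <- if (mode == "inverted") quadrat_table$p99 - quadrat_table$h_c
         else quadrat_table$p99
  quadrats <- data.frame(quadrat_id = quadrat_table$quadrat_id,
                         plot_id = quadrat_table$plot_id,
                         h_g = h_g, stringsAsFactors = FALSE)
  agg <- aggregate(h_g ~ plot_id, data = quadrats, FUN = mean)
  names(agg)[2] <- "h_gf"
  structure(list(plots = agg[order(agg$plot_id), , drop = FALSE],
                 quadrats = quadrats, mode = mode),
            class = "ground_model")
}

#' @export
print.ground_model <- function(x, ...) {
  cat(sprintf("ground_model (%s): %d plots, h_gf range [%.3f, %.3f] m\n",
              x$mode, nrow(x$plots), min(x$plots$h_gf), max(x$plots$h_gf)))
  invisible(x)
}
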