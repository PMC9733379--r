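## Canopy segmentation and point-density statistics: the 2-D density matrix,
## its occupancy-ratio summary g(eps), and the canopy maximum diameter.

#' Keep only above-ground canopy points
#'
#' Retains points whose relative height `e` strictly exceeds the threshold
#' (default 0; a small positive buffer suppresses ground noise).
#'
#' @param cloud `point_cloud` with relative heights attached.
#' @param threshold Ground threshold in metres.
#' @return The filtered `point_cloud` (canopy subset, `e` retained).
#' @export
segment_above_ground <- function(cloud, threshold = 0) {
  if (!inherits(cloud, "point_cloud") || is.null(cloud$e))
    stop_validation("cloud has no relative heights; run relative_heights() first")
  keep <- cloud$e > threshold
  point_cloud(cloud$coords[keep, , drop = FALSE], cloud$frame,
              local_frame = cloud$local_frame, e = cloud$e[keep])
}

#' Two-dimensional point-density matrix
#'
#' Bins canopy points into square cells of edge `epsilon` on a vertical
#' slice (horizontal coordinate vs. relative height `e`, the default) or on
#' the horizontal x-y plane, and converts counts to densities
#' \eqn{a_{u,v} = card(R_{u,v}) / \epsilon^2} (points per square metre).
#' Bins are half-open, anchored at each axis minimum; points on the extreme
#' upper boundary are closed into the last bin so the mass identity
#' \eqn{\sum a_{u,v} \epsilon^2 = n} holds exactly.
#'
#' @param canopy `point_cloud` with `e` (for `"xe"`/`"ye"` axes) or any
#'   local cloud (for `"xy"`).
#' @param epsilon Cell edge length in metres; default 1 (the cotton planting
#'   row width).
#' @param axes `"xe"` (default), `"ye"`, or `"xy"`.
#' @param extents Optional list with `u = c(min, max)` and `v = c(min, max)`
#'   axis extents; defaults to the data range.
#' @return A `density_grid`: matrix `a` (u indexing rows), `epsilon`, axes
#'   and extents.
#' @export
density_grid <- function(canopy, epsilon = 1, axes = c("xe", "ye", "xy"),
                         extents = NULL) {
  axes <- match.arg(axes)
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_validation("epsilon must be a positive length in metres")
  m <- cloud_coords(canopy)
  if (nrow(m) == 0) stop_validation("cannot grid an empty canopy")
  coord_u <- switch(axes, xe = m[, 1], ye = m[, 2], xy = m[, 1])
  coord_v <- switch(axes,
    xy = m[, 2],
    {
      if (!inherits(canopy, "point_cloud") || is.null(canopy$e))
        stop_validation("axes '%s' need relative heights e on the cloud", axes)
      canopy$e
    })
  if (is.null(extents))
    extents <- list(u = range(coord_u), v = range(coord_v))
  nu <- max(1L, ceiling((extents$u[2] - extents$u[1]) / epsilon - 1e-9))
  nv <- max(1L, ceiling((extents$v[2] - extents$v[1]) / epsilon - 1e-9))
  iu <- pmin(pmax(floor((coord_u - extents$u[1]) / epsilon), 0) + 1L, nu)
  iv <- pmin(pmax(floor((coord_v - extents$v[1]) / epsilon), 0) + 1L, nv)
  counts <- matrix(0, nu, nv)
  tab <- table(factor(iu + (iv - 1) * nu, levels = seq_len(nu * nv)))
  counts[] <- as.integer(tab)
  structure(list(a = counts / epsilon^2, epsilon = epsilon, axes = axes,
                 extents = extents, n_points = nrow(m)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density_grid: %d x %d cells, epsilon %.3g m, axes %s, %d points\n",
              nrow(x$a), ncol(x$a), x$epsilon, x$axes, x$n_points))
  invisible(x)
}

#' Occupancy ratio of a density matrix
#'
#' The fraction of cells whose density is at least 0.2 times the mean
#' density, the mean being taken over all cells of the matrix including
#' empty ones. Summarizes how evenly the canopy fills its bounding region;
#' a dense uniform canopy scores 1.
#'
#' @param grid A `density_grid`.
#' @return A fraction in [0, 1]. An all-zero grid returns 1 (every cell
#'   trivially meets the `>=` threshold) with a warning.
#' @export
occupancy_ratio <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  a <- grid$a
  if (length(a) == 0) stop_validation("empty density grid")
  rho <- mean(a)
  if (rho == 0)
    warning("all-zero density grid: occupancy ratio is degenerate (1)")
  mean(a >= 0.2 * rho)
}

#' Maximum horizontal canopy diameter
#'
#' The largest pairwise horizontal (x-y) distance among canopy points,
#' optionally restricted to a rectangular region. Computed on the 2-D convex
#' hull, so it scales to large clouds; `method = "bbox"` returns the
#' bounding-box diagonal instead.
#'
#' @param canopy `point_cloud` or coordinate matrix (local frame).
#' @param region Optional `c(xmin, ymin, xmax, ymax)` restriction.
#' @param method `"hull"` (exact diameter, default) or `"bbox"`.
#' @return Diameter in metres.
#' @export
canopy_diameter <- function(canopy, region = NULL, method = c("hull", "bbox")) {
  method <- match.arg(method)
  m <- cloud_coords(canopy)
  xy <- m[, 1:2, drop = FALSE]
  if (!is.null(region)) {
    keep <- xy[, 1] >= region[1] & xy[, 1] <= region[3] &
            xy[, 2] >= region[2] & xy[, 2] <= region[4]
    xy <- xy[keep, , drop = FALSE]
  }
  if (nrow(xy) < 2)
    stop_validation("canopy diameter needs at least 2 points in the region")
  if (method == "bbox")
    return(sqrt(diff(range(xy[, 1]))^2 + diff(range(xy[, 2]))^2))
  hull <- xy[unique(grDevices::chull(xy)), , drop = FALSE]
  if (nrow(hull) < 2) hull <- unique(xy)  # all points coincident-ish
  if (nrow(hull) < 2) return(0)
  d2 <- as.matrix(dist(hull))
  max(d2)
}

#' Per-quadrat canopy descriptors
#'
#' For every quadrat of a layout, computes the occupancy ratio `g` of a
#' per-quadrat density grid (vertical x-e slice at cell size `epsilon`) and
#' the maximum canopy diameter `d_t` of the quadrat's canopy points. A 1 m
#' grid cell would collapse a 1 x 1 m quadrat to a single cell, so the
#' descriptor grid defaults to 0.2 m cells.
#'
#' The vertical span of the descriptor grid is fixed (1 m by default, the
#' canopy height scale of the crop) so that `g` is comparable across
#' quadrats instead of depending on each quadrat's own tallest point.
#'
#' @param canopy `point_cloud` with relative heights `e` (above-ground
#'   canopy subset).
#' @param layout A `plot_layout`.
#' @param epsilon Density-grid cell size for the `g` descriptor (m).
#' @param axes Density-grid axes passed to [density_grid()].
#' @param v_span Fixed vertical extent `c(min, max)` of the descriptor grid
#'   (m of relative height).
#' @return Data frame: `quadrat_id`, `plot_id`, `g`, `d_t`, `n_points`.
#'   Quadrats with no canopy points get `g = 0`; with fewer than 2 points,
#'   `d_t = 0`.
#' @export
quadrat_features <- function(canopy, layout, epsilon = 0.2, axes = "xe",
                             v_span = c(0, 1)) {
  stopifnot(inherits(layout, "plot_layout"))
  if (!inherits(canopy, "point_cloud") || is.null(canopy$e))
    stop_validation("canopy cloud must carry relative heights e")
  m <- canopy$coords; e <- canopy$e
  q <- layout$quadrats
  g <- d_t <- npts <- numeric(nrow(q))
  for (i in seq_len(nrow(q))) {
    inq <- m[, 1] >= q$xmin[i] & m[, 1] <= q$xmax[i] &
           m[, 2] >= q$ymin[i] & m[, 2] <= q$ymax[i]
    npts[i] <- sum(inq)
    if (npts[i] == 0) { g[i] <- 0; d_t[i] <- 0; next }
    sub <- point_cloud(m[inq, , drop = FALSE], canopy$frame, e = e[inq])
    grid <- density_grid(sub, epsilon = epsilon, axes = axes,
                         extents = list(u = c(q$xmin[i], q$xmax[i]),
                                        v = v_span))
    g[i] <- occupancy_ratio(grid)
    d_t[i] <- if (npts[i] >= 2) canopy_diameter(sub) else 0
  }
  data.frame(quadrat_id = q$quadrat_id, plot_id = q$plot_id,
             g = g, d_t = d_t, n_points = npts, stringsAsFactors = FALSE)
}
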