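## Digital surface model rasterization and percentile-based canopy height.

#' Plot/quadrat layout of a field trial
#'
#' @param plots Data frame: `plot_id`, `xmin`, `ymin`, `xmax`, `ymax` (m).
#' @param quadrats Data frame: `quadrat_id`, `plot_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (m). Every quadrat must lie inside its plot.
#' @return A `plot_layout` object.
#' @export
plot_layout <- function(plots, quadrats) {
  need_p <- c("plot_id", "xmin", "ymin", "xmax", "ymax")
  need_q <- c("quadrat_id", need_p)
  if (!all(need_p %in% names(plots)) || !all(need_q %in% names(quadrats)))
    stop_validation("layout tables missing required columns")
  if (anyDuplicated(plots$plot_id))
    stop_validation("duplicate plot ids in layout")
  idx <- match(quadrats$plot_id, plots$plot_id)
  if (anyNA(idx)) stop_validation("quadrat references unknown plot id")
  inside <- quadrats$xmin >= plots$xmin[idx] & quadrats$xmax <= plots$xmax[idx] &
            quadrats$ymin >= plots$ymin[idx] & quadrats$ymax <= plots$ymax[idx]
  if (!all(inside))
    stop_validation("quadrat(s) outside their plot: %s",
                    paste(quadrats$quadrat_id[!inside], collapse = ", "))
  structure(list(plots = plots, quadrats = quadrats), class = "plot_layout")
}

#' @export
print.plot_layout <- function(x, ...) {
  cat(sprintf("plot_layout: %d plots, %d quadrats\n",
              nrow(x$plots), nrow(x$quadrats)))
  invisible(x)
}

#' Rasterize a local-frame point cloud into a digital surface model
#'
#' Each grid cell takes the maximum elevation of the points whose (x, y)
#' position falls inside it (half-open cell intervals; points on the extreme
#' upper boundary are closed into the last cell so every point is binned).
#' Cells that receive no point are filled from their nearest non-empty cell
#' by iterative dilation (Chebyshev-nearest; equidistant neighbours are
#' averaged), so downstream percentiles see a complete surface.
#'
#' @param cloud `point_cloud` in the LOCAL frame, or n x 3 matrix.
#' @param cell_size Cell edge length in metres (default 0.05).
#' @param use_e Rasterize per-point relative heights `e` instead of raw z.
#' @param fill `"nearest"` (default) or `"none"` (keeps NA cells).
#' @return A `dsm_grid`: `values` (nx x ny matrix, x indexing rows), cell
#'   size, grid origin, and the fill method used.
#' @export
rasterize_dsm <- function(cloud, cell_size = 0.05, use_e = FALSE,
                          fill = c("nearest", "none")) {
  fill <- match.arg(fill)
  if (cell_size <= 0) stop_validation("cell_size must be positive")
  m <- cloud_coords(cloud)
  if (nrow(m) == 0) stop_validation("cannot rasterize an empty cloud")
  z <- if (use_e) {
    if (!inherits(cloud, "point_cloud") || is.null(cloud$e))
      stop_validation("use_e = TRUE but the cloud has no relative heights")
    cloud$e
  } else m[, 3]
  x0 <- min(m[, 1]); y0 <- min(m[, 2])
  nx <- max(1L, as.integer(floor((max(m[, 1]) - x0) / cell_size)) + 1L)
  ny <- max(1L, as.integer(floor((max(m[, 2]) - y0) / cell_size)) + 1L)
  ix <- pmin(as.integer(floor((m[, 1] - x0) / cell_size)) + 1L, nx)
  iy <- pmin(as.integer(floor((m[, 2] - y0) / cell_size)) + 1L, ny)
  cell <- ix + (iy - 1L) * nx
  # per-cell max without hashing: sort by (cell, z) and keep each cell's last
  o <- order(cell, z)
  oc <- cell[o]
  keep <- c(oc[-1] != oc[-length(oc)], TRUE)
  vals <- matrix(NA_real_, nx, ny)
  vals[oc[keep]] <- z[o][keep]
  n_empty <- sum(is.na(vals))
  if (fill == "nearest" && n_empty > 0) vals <- fill_nearest(vals)
  structure(list(values = vals, cell_size = cell_size, x0 = x0, y0 = y0,
                 nx = nx, ny = ny, fill = fill, n_empty = n_empty),
            class = "dsm_grid")
}

# Iterative 8-neighbour dilation: each pass, NA cells adjacent to filled
# cells take the mean of their filled neighbours. Converges in
# O(max empty-run length) passes.
fill_nearest <- function(vals) {
  nx <- nrow(vals); ny <- ncol(vals)
  while (anyNA(vals)) {
    filled <- !is.na(vals)
    acc <- matrix(0, nx, ny); cnt <- matrix(0L, nx, ny)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      sx <- max(1, 1 + dx):min(nx, nx + dx)
      tx <- max(1, 1 - dx):min(nx, nx - dx)
      sy <- max(1, 1 + dy):min(ny, ny + dy)
      ty <- max(1, 1 - dy):min(ny, ny - dy)
      src_ok <- filled[sx, sy, drop = FALSE]
      v <- vals[sx, sy, drop = FALSE]
      v[!src_ok] <- 0
      acc[tx, ty] <- acc[tx, ty] + v
      cnt[tx, ty] <- cnt[tx, ty] + src_ok
    }
    take <- !filled & cnt > 0L
    if (!any(take)) stop_numeric("nearest-neighbour fill failed to progress")
    vals[take] <- acc[take] / cnt[take]
  }
  vals
}

#' @export
print.dsm_grid <- function(x, ...) {
  cat(sprintf("dsm_grid: %d x %d cells of %.3f m (origin %.2f, %.2f), fill %s\n",
              x$nx, x$ny, x$cell_size, x$x0, x$y0, x$fill))
  invisible(x)
}

# Linearized indices of cells whose centre lies in [xmin,xmax] x [ymin,ymax].
dsm_region_cells <- function(dsm, region) {
  cx <- dsm$x0 + (seq_len(dsm$nx) - 0.5) * dsm$cell_size
  cy <- dsm$y0 + (seq_len(dsm$ny) - 0.5) * dsm$cell_size
  ix <- which(cx >= region[1] & cx <= region[3])
  iy <- which(cy >= region[2] & cy <= region[4])
  list(ix = ix, iy = iy)
}

#' Percentile upper boundary of a DSM region
#'
#' The canopy upper boundary of a region is a high percentile (99th by
#' default) of the DSM cell values whose cell centres fall inside the
#' region. Percentiles use the linear-interpolation definition
#' (\code{\link[stats]{quantile}} type 7).
#'
#' @param dsm A `dsm_grid`.
#' @param region Numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param percentile Percentile in (0, 100]; default 99.
#' @return Upper-boundary elevation (m).
#' @export
upper_boundary_p99 <- function(dsm, region, percentile = 99) {
  stopifnot(inherits(dsm, "dsm_grid"))
  if (percentile <= 0 || percentile > 100)
    stop_validation("percentile must be in (0, 100]")
  cells <- dsm_region_cells(dsm, region)
  if (length(cells$ix) == 0 || length(cells$iy) == 0)
    stop_validation("region [%g, %g] x [%g, %g] covers no DSM cell centres",
                    region[1], region[3], region[2], region[4])
  v <- dsm$values[cells$ix, cells$iy]
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop_validation("region contains only empty (unfilled) DSM cells")
  unname(quantile(v, percentile / 100, type = 7))
}

#' Plot and quadrat canopy heights from a DSM and a ground model
#'
#' For every plot, height is the percentile upper boundary of the plot region
#' minus the plot ground elevation: `h_f = P99_f - h_gf`. Quadrat-level
#' estimates `h_e = P99_i - h_gf` are returned for evaluation against
#' manually measured heights.
#'
#' @param dsm A `dsm_grid`.
#' @param ground A `ground_model` covering every plot in the layout.
#' @param layout A `plot_layout`.
#' @param percentile Upper-boundary percentile (default 99).
#' @return A `height_estimate` list with data frames `$plots`
#'   (plot_id, p99, h_ground, h_f) and `$quadrats`
#'   (quadrat_id, plot_id, p99, h_ground, h_e).
#' @export
estimate_heights <- function(dsm, ground, layout, percentile = 99) {
  stopifnot(inherits(ground, "ground_model"), inherits(layout, "plot_layout"))
  missing_plots <- setdiff(layout$plots$plot_id, ground$plots$plot_id)
  if (length(missing_plots))
    stop_validation("no ground elevation for plot(s): %s",
                    paste(missing_plots, collapse = ", "))
  gp <- ground$plots$h_gf[match(layout$plots$plot_id, ground$plots$plot_id)]
  p99_f <- vapply(seq_len(nrow(layout$plots)), function(i) {
    b <- layout$plots[i, ]
    upper_boundary_p99(dsm, c(b$xmin, b$ymin, b$xmax, b$ymax), percentile)
  }, 0)
  plots <- data.frame(plot_id = layout$plots$plot_id, p99 = p99_f,
                      h_ground = gp, h_f = p99_f - gp,
                      stringsAsFactors = FALSE)
  gq <- gp[match(layout$quadrats$plot_id, layout$plots$plot_id)]
  p99_i <- vapply(seq_len(nrow(layout$quadrats)), function(i) {
    b <- layout$quadrats[i, ]
    upper_boundary_p99(dsm, c(b$xmin, b$ymin, b$xmax, b$ymax), percentile)
  }, 0)
  quadrats <- data.frame(quadrat_id = layout$quadrats$quadrat_id,
                         plot_id = layout$quadrats$plot_id,
                         p99 = p99_i, h_ground = gq, h_e = p99_i - gq,
                         stringsAsFactors = FALSE)
  structure(list(plots = plots, quadrats = quadrats, percentile = percentile),
            class = "height_estimate")
}

#' @export
print.height_estimate <- function(x, ...) {
  cat(sprintf("height_estimate: %d plots (h_f %.3f-%.3f m), %d quadrats\n",
              nrow(x$plots), min(x$plots$h_f), max(x$plots$h_f),
              nrow(x$quadrats)))
  invisible(x)
}
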