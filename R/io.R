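## File formats: XYZ-CSV and ASCII PLY point clouds (with a JSON sidecar
## carrying the local frame for LOCAL exports), layout GeoJSON, and the
## quadrat measurements CSV.

frame_sidecar_path <- function(path) paste0(path, ".frame.json")

write_frame_sidecar <- function(frame, path) {
  jsonlite::write_json(list(origin_geo = as.list(frame$origin_geo),
                            origin_ecef = frame$origin_ecef,
                            rotation = frame$rotation),
                       frame_sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_frame_sidecar <- function(path) {
  sc <- frame_sidecar_path(path)
  if (!file.exists(sc)) return(NULL)
  obj <- jsonlite::read_json(sc, simplifyVector = TRUE)
  local_frame(obj$origin_geo$lat, obj$origin_geo$lon, obj$origin_geo$h)
}

#' Read and write georeferenced point clouds
#'
#' Supported formats: `"xyz-csv"` (header names the frame: columns
#' `lat,lon,h` for WGS84 or `x,y,z` for Cartesian frames) and `"ply"`
#' (ASCII PLY with vertex properties x, y, z and a `comment frame <TAG>`
#' header line). LOCAL-frame files carry their frame in a JSON sidecar
#' (`<path>.frame.json`) so they remain invertible to WGS84.
#'
#' @param path File path.
#' @param format `"xyz-csv"` or `"ply"`; inferred from the extension when
#'   missing.
#' @param frame Frame tag override for Cartesian files without a sidecar.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = NULL, frame = NULL) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  if (is.null(format))
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz-csv"
  if (!format %in% c("xyz-csv", "ply"))
    stop_io("unknown point cloud format: %s", format)
  if (format == "ply") return(read_ply(path, frame))
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop_io("failed to parse %s: %s", path, conditionMessage(e)))
  lower <- tolower(names(df))
  if (all(c("lat", "lon", "h") %in% lower)) {
    m <- as.matrix(df[match(c("lat", "lon", "h"), lower)])
    tag <- "WGS84"
  } else if (all(c("x", "y", "z") %in% lower)) {
    m <- as.matrix(df[match(c("x", "y", "z"), lower)])
    sidecar <- read_frame_sidecar(path)
    tag <- frame %||% if (!is.null(sidecar)) "LOCAL" else
      stop_io("%s has x/y/z columns but no frame declaration (sidecar or 'frame=')",
              path)
  } else {
    stop_io("%s: header must name lat,lon,h or x,y,z; got %s",
            path, paste(names(df), collapse = ","))
  }
  bad <- which(!complete.cases(m))
  if (length(bad))
    stop_io("%s: malformed coordinate row(s) at data line(s) %s",
            path, paste(utils::head(bad, 5), collapse = ", "))
  e <- if ("e" %in% lower) df[[match("e", lower)]] else NULL
  point_cloud(m, tag, local_frame = read_frame_sidecar(path), e = e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_point_cloud
#' @param cloud A `point_cloud` to write.
#' @export
write_point_cloud <- function(cloud, path, format = NULL) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(format))
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz-csv"
  if (format == "ply") {
    write_ply(cloud, path)
  } else {
    df <- as.data.frame(cloud$coords)
    if (!is.null(cloud$e)) df$e <- cloud$e
    utils::write.csv(df, path, row.names = FALSE)
  }
  if (cloud$frame == "LOCAL" && !is.null(cloud$local_frame))
    write_frame_sidecar(cloud$local_frame, path)
  invisible(path)
}

read_ply <- function(path, frame = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || lines[1] != "ply")
    stop_io("%s: not a PLY file (missing 'ply' magic)", path)
  end <- match("end_header", lines)
  if (is.na(end)) stop_io("%s: PLY header has no end_header", path)
  header <- lines[seq_len(end)]
  if (!any(grepl("^format ascii", header)))
    stop_io("%s: only ASCII PLY is supported", path)
  nv <- suppressWarnings(as.integer(sub("^element vertex ", "",
                                        grep("^element vertex ", header, value = TRUE))))
  if (length(nv) != 1 || is.na(nv))
    stop_io("%s: PLY header lacks a vertex element count", path)
  props <- sub("^property \\S+ ", "", grep("^property ", header, value = TRUE))
  if (length(props) < 3 || !identical(props[1:3], c("x", "y", "z")))
    stop_io("%s: first three vertex properties must be x, y, z", path)
  tag <- sub("^comment frame ", "", grep("^comment frame ", header, value = TRUE))
  tag <- if (length(tag)) tag else frame %||% "LOCAL"
  body <- lines[seq(end + 1L, length.out = nv)]
  vals <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(vals)
  if (any(nfield < 3))
    stop_io("%s: malformed vertex row(s) at line(s) %s", path,
            paste(utils::head(which(nfield < 3) + end, 5), collapse = ", "))
  m <- matrix(as.numeric(unlist(lapply(vals, `[`, 1:3))), ncol = 3, byrow = TRUE)
  if (anyNA(m))
    stop_io("%s: non-numeric vertex coordinates", path)
  e <- if (length(props) >= 4 && props[4] == "e")
    as.numeric(vapply(vals, `[`, "", 4)) else NULL
  point_cloud(m, tag, local_frame = read_frame_sidecar(path), e = e)
}

write_ply <- function(cloud, path) {
  m <- cloud$coords
  has_e <- !is.null(cloud$e)
  header <- c("ply", "format ascii 1.0",
              paste("comment frame", cloud$frame),
              sprintf("element vertex %d", nrow(m)),
              "property double x", "property double y", "property double z",
              if (has_e) "property double e",
              "end_header")
  body <- if (has_e)
    sprintf("%.10g %.10g %.10g %.10g", m[, 1], m[, 2], m[, 3], cloud$e)
  else sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write plot layouts as GeoJSON
#'
#' Plots and quadrats are stored as a GeoJSON FeatureCollection of
#' axis-aligned Polygon features with `kind` ("plot"/"quadrat"), `id` and
#' `plot_id` properties; coordinates are local-frame metres.
#'
#' @param layout A [plot_layout()].
#' @param path File path.
#' @return `read_layout()` returns a `plot_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "plot_layout"))
  rect_feature <- function(kind, id, plot_id, b) {
    list(type = "Feature",
         properties = list(kind = kind, id = id, plot_id = plot_id),
         geometry = list(type = "Polygon", coordinates = list(list(
           c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]), c(b[1], b[4]),
           c(b[1], b[2])))))
  }
  feats <- c(
    lapply(seq_len(nrow(layout$plots)), function(i) {
      p <- layout$plots[i, ]
      rect_feature("plot", p$plot_id, p$plot_id,
                   c(p$xmin, p$ymin, p$xmax, p$ymax))
    }),
    lapply(seq_len(nrow(layout$quadrats)), function(i) {
      q <- layout$quadrats[i, ]
      rect_feature("quadrat", q$quadrat_id, q$plot_id,
                   c(q$xmin, q$ymin, q$xmax, q$ymax))
    }))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop_io("%s: not a GeoJSON FeatureCollection", path)
  rows <- lapply(obj$features, function(f) {
    coords <- f$geometry$coordinates[[1]]
    xs <- vapply(coords, function(c) as.numeric(c[[1]]), 0)
    ys <- vapply(coords, function(c) as.numeric(c[[2]]), 0)
    data.frame(kind = f$properties$kind, id = f$properties$id,
               plot_id = f$properties$plot_id,
               xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  plots <- all[all$kind == "plot", c("id", "xmin", "ymin", "xmax", "ymax")]
  names(plots)[1] <- "plot_id"
  quadrats <- all[all$kind == "quadrat",
                  c("id", "plot_id", "xmin", "ymin", "xmax", "ymax")]
  names(quadrats)[1] <- "quadrat_id"
  plot_layout(plots, quadrats)
}

#' Read a quadrat measurements table
#'
#' Expects columns `quadrat_id`, `plot_id`, `xmin`, `ymin`, `xmax`, `ymax`,
#' `h_c` (m) and optionally `lai`.
#'
#' @param path CSV file path.
#' @return Data frame of measurements.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("quadrat_id", "plot_id", "xmin", "ymin", "xmax", "ymax", "h_c")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_io("%s: missing measurement column(s): %s", path,
            paste(miss, collapse = ", "))
  df
}
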