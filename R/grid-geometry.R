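# Mean Earth radius (m), IUGG value; shared by the projection and the
# geodesic helpers so projected and great-circle quantities are consistent.
.EARTH_RADIUS <- 6371008.8

#' Local metric projection for a study area
#'
#' Builds an equidistant-cylindrical projection centred on a lon/lat bounding
#' box: \code{x = R cos(lat0) (lon - lon0)}, \code{y = R (lat - lat0)} (radians).
#' Over a few degrees of latitude the total-area distortion relative to the
#' geodesic area is far below 1\%, which is all the 1-km analysis grid needs.
#'
#' @param extent named numeric vector with \code{lon_min}, \code{lon_max},
#'   \code{lat_min}, \code{lat_max} in decimal degrees.
#' @return an object of class \code{local_proj}.
#' @export
local_projection <- function(extent) {
  extent <- check_extent(extent)
  structure(list(
    lon0 = mean(extent[c("lon_min", "lon_max")]),
    lat0 = mean(extent[c("lat_min", "lat_max")]),
    R = .EARTH_RADIUS
  ), class = "local_proj")
}

check_extent <- function(extent) {
  need <- c("lon_min", "lon_max", "lat_min", "lat_max")
  if (!all(need %in% names(extent))) {
    stop("extent must have names ", paste(need, collapse = ", "))
  }
  extent <- extent[need]
  if (!all(is.finite(extent))) stop("extent must be finite")
  if (extent["lon_min"] >= extent["lon_max"] ||
      extent["lat_min"] >= extent["lat_max"]) {
    stop("degenerate or inverted extent")
  }
  if (extent["lat_min"] < -90 || extent["lat_max"] > 90 ||
      extent["lon_min"] < -180 || extent["lon_max"] > 360) {
    stop("extent outside valid lon/lat range")
  }
  extent
}

#' Project lon/lat to local metric coordinates
#'
#' @param proj a \code{local_proj} object.
#' @param lon,lat coordinates in decimal degrees.
#' @return list with numeric vectors \code{x}, \code{y} in metres.
#' @export
project_lonlat <- function(proj, lon, lat) {
  d2r <- pi / 180
  list(
    x = proj$R * cos(proj$lat0 * d2r) * (lon - proj$lon0) * d2r,
    y = proj$R * (lat - proj$lat0) * d2r
  )
}

#' Inverse of [project_lonlat()]
#' @inheritParams project_lonlat
#' @param x,y metric coordinates (m).
#' @return list with numeric vectors \code{lon}, \code{lat} in degrees.
#' @export
unproject_xy <- function(proj, x, y) {
  r2d <- 180 / pi
  list(
    lon = proj$lon0 + x / (proj$R * cos(proj$lat0 * pi / 180)) * r2d,
    lat = proj$lat0 + y / proj$R * r2d
  )
}

#' Regular metric grid over an area of interest
#'
#' Lays a regular grid of square cells over the projected bounding box.
#' Cell membership is half-open, \code{[x, x + size) x [y, y + size)}, and
#' cell ids are stable row-major integers counted from the south-west corner.
#'
#' @param extent lon/lat bounding box (see [local_projection()]).
#' @param cell_size cell edge length in metres (default 1000).
#' @return an object of class \code{grid_geometry}.
#' @export
grid_geometry <- function(extent, cell_size = 1000) {
  extent <- check_extent(extent)
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be positive")
  proj <- local_projection(extent)
  ll <- project_lonlat(proj, extent["lon_min"], extent["lat_min"])
  ur <- project_lonlat(proj, extent["lon_max"], extent["lat_max"])
  nx <- ceiling((ur$x - ll$x) / cell_size - 1e-9)
  ny <- ceiling((ur$y - ll$y) / cell_size - 1e-9)
  if (nx < 1 || ny < 1) stop("degenerate extent: no cells")
  structure(list(
    xmin = unname(ll$x), ymin = unname(ll$y),
    nx = as.integer(nx), ny = as.integer(ny),
    cell_size = cell_size, proj = proj, extent = extent
  ), class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("grid_geometry: %d x %d cells of %g m (%d cells)\n",
              x$nx, x$ny, x$cell_size, x$nx * x$ny))
  invisible(x)
}

n_cells <- function(geom) geom$nx * geom$ny

#' Cell centres of a grid
#' @param geom a \code{grid_geometry}.
#' @return data.frame with \code{cell_id}, metric \code{x}, \code{y} and
#'   geographic \code{lon}, \code{lat} of every cell centre, row-major from
#'   the south-west corner.
#' @export
cell_centres <- function(geom) {
  ix <- rep(seq_len(geom$nx), times = geom$ny)
  iy <- rep(seq_len(geom$ny), each = geom$nx)
  x <- geom$xmin + (ix - 0.5) * geom$cell_size
  y <- geom$ymin + (iy - 0.5) * geom$cell_size
  ll <- unproject_xy(geom$proj, x, y)
  data.frame(cell_id = seq_along(x), x = x, y = y, lon = ll$lon, lat = ll$lat)
}

#' Cell id containing metric points (half-open membership)
#' @param geom a \code{grid_geometry}.
#' @param x,y metric coordinates.
#' @return integer cell ids; \code{NA} for points outside the grid.
#' @export
cell_at_xy <- function(geom, x, y) {
  ix <- floor((x - geom$xmin) / geom$cell_size) + 1
  iy <- floor((y - geom$ymin) / geom$cell_size) + 1
  ok <- ix >= 1 & ix <= geom$nx & iy >= 1 & iy <= geom$ny
  id <- ifelse(ok, (iy - 1) * geom$nx + ix, NA_integer_)
  as.integer(id)
}

#' @rdname cell_at_xy
#' @param lon,lat geographic coordinates (degrees).
#' @export
cell_at_lonlat <- function(geom, lon, lat) {
  p <- project_lonlat(geom$proj, lon, lat)
  cell_at_xy(geom, p$x, p$y)
}

# ---- raster layer: a matrix bound to a grid_geometry --------------------

#' Raster layer on a grid
#'
#' A raster layer is a numeric vector of cell values (row-major from the
#' south-west, matching [cell_centres()]) bound to a \code{grid_geometry}.
#'
#' @param geom a \code{grid_geometry}.
#' @param values numeric vector of length \code{nx * ny}, or a single value.
#' @param name layer name.
#' @return an object of class \code{grid_raster}.
#' @export
grid_raster <- function(geom, values, name = "layer") {
  if (length(values) == 1) values <- rep(values, n_cells(geom))
  if (length(values) != n_cells(geom)) {
    stop("values length ", length(values), " != number of cells ", n_cells(geom))
  }
  structure(list(geom = geom, values = as.numeric(values), name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster '%s': %d x %d; range [%.4g, %.4g], %d NA\n",
              x$name, x$geom$nx, x$geom$ny,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Raster values as a matrix (rows = y from south, cols = x from west)
#' @param r a \code{grid_raster}.
#' @export
raster_matrix <- function(r) {
  matrix(r$values, nrow = r$geom$ny, ncol = r$geom$nx, byrow = TRUE)
}

raster_from_matrix <- function(geom, m, name = "layer") {
  grid_raster(geom, as.numeric(t(m)), name)
}

same_geometry <- function(a, b, tol = 1e-6) {
  isTRUE(all.equal(a$xmin, b$xmin, tolerance = tol)) &&
    isTRUE(all.equal(a$ymin, b$ymin, tolerance = tol)) &&
    a$nx == b$nx && a$ny == b$ny &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = tol))
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a$geom, b$geom)) stop("rasters are not co-registered")
  invisible(TRUE)
}

#' Bilinear extraction of raster values at points
#'
#' Interpolates between the four cell-centre nodes surrounding each query
#' point. Exact at nodes. Points outside the convex hull of the cell centres
#' get \code{NA} with a warning.
#'
#' @param r a \code{grid_raster}.
#' @param lon,lat query coordinates in degrees (or supply metric \code{x,y}).
#' @param x,y metric query coordinates, used when \code{lon} is missing.
#' @return numeric vector of interpolated values.
#' @export
extract_bilinear <- function(r, lon, lat, x = NULL, y = NULL) {
  g <- r$geom
  if (missing(lon) || is.null(lon)) {
    if (is.null(x)) stop("supply lon/lat or x/y")
  } else {
    p <- project_lonlat(g$proj, lon, lat)
    x <- p$x; y <- p$y
  }
  # node coordinates are cell centres
  fx <- (x - (g$xmin + 0.5 * g$cell_size)) / g$cell_size
  fy <- (y - (g$ymin + 0.5 * g$cell_size)) / g$cell_size
  ix <- floor(fx); iy <- floor(fy)
  inside <- fx >= -1e-9 & fx <= g$nx - 1 + 1e-9 &
            fy >= -1e-9 & fy <= g$ny - 1 + 1e-9
  ix <- pmin(pmax(ix, 0), g$nx - 2)
  iy <- pmin(pmax(iy, 0), g$ny - 2)
  tx <- fx - ix; ty <- fy - iy
  id <- function(i, j) j * g$nx + i + 1  # 0-based i (x), j (y)
  v <- (1 - tx) * (1 - ty) * r$values[id(ix, iy)] +
       tx       * (1 - ty) * r$values[id(ix + 1, iy)] +
       (1 - tx) * ty       * r$values[id(ix, iy + 1)] +
       tx       * ty       * r$values[id(ix + 1, iy + 1)]
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside the raster node hull: NA returned")
    v[!inside] <- NA_real_
  }
  v
}

#' Cellwise mean of raster layers over a survey window
#'
#' Averages a list of co-registered rasters whose dates fall inside a window,
#' excluding missing values cell by cell (per-cell divisor).
#'
#' @param rasters list of \code{grid_raster} layers.
#' @param dates \code{Date} vector, one per raster.
#' @param window length-2 \code{Date} vector (inclusive).
#' @return a \code{grid_raster} of cellwise means.
#' @export
average_over_period <- function(rasters, dates, window) {
  stopifnot(length(rasters) == length(dates))
  dates <- as.Date(dates); window <- as.Date(window)
  keep <- dates >= window[1] & dates <= window[2]
  if (!any(keep)) stop("no rasters fall inside the averaging window")
  rs <- rasters[keep]
  for (r in rs[-1]) stop_if_geometry_mismatch(rs[[1]], r)
  vals <- vapply(rs, function(r) r$values, numeric(n_cells(rs[[1]]$geom)))
  vals <- matrix(vals, ncol = length(rs))
  s <- rowSums(vals, na.rm = TRUE)
  n <- rowSums(!is.na(vals))
  out <- ifelse(n > 0, s / n, NA_real_)
  grid_raster(rs[[1]]$geom, out, rs[[1]]$name)
}

# ---- plain-text raster serialization (ESRI ASCII grid) ------------------

#' Write a raster layer as an ESRI ASCII grid
#'
#' Plain-text raster serialization; the grid registration is recorded via
#' \code{xllcorner}/\code{yllcorner} in the local metric CRS, whose lon/lat
#' origin is stored in companion header comments.
#'
#' @param r a \code{grid_raster}.
#' @param path output file path.
#' @export
write_ascii_grid <- function(r, path) {
  g <- r$geom
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.6f", g$xmin),
    sprintf("yllcorner %.6f", g$ymin),
    sprintf("cellsize %.6f", g$cell_size),
    "NODATA_value -9999"
  ), con)
  m <- raster_matrix(r)
  m[!is.finite(m)] <- -9999
  # ASCII grids store rows north to south
  for (i in rev(seq_len(nrow(m)))) {
    writeLines(paste(formatC(m[i, ], format = "g", digits = 10), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid()]
#' @param path file path.
#' @param geom the \code{grid_geometry} the layer belongs to.
#' @param name layer name.
#' @export
read_ascii_grid <- function(path, geom, name = "layer") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) as.numeric(sub(paste0(key, " "), "", hdr[grep(key, hdr)]))
  if (val("ncols") != geom$nx || val("nrows") != geom$ny) {
    stop("grid dimensions in ", path, " do not match the supplied geometry")
  }
  rows <- lapply(lines[-(1:6)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, rev(rows))  # back to south-first rows
  m[m == -9999] <- NA_real_
  raster_from_matrix(geom, m, name)
}
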