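# 1-km2 analysis grid: effort, sightings, labels, covariates, prediction area.

#' Build the analysis grid over an area of interest
#'
#' Thin wrapper around [grid_geometry()] kept as the canonical entry point:
#' regular square cells in the local metric projection, half-open membership,
#' stable row-major cell ids from the south-west corner.
#'
#' @param aoi lon/lat bounding box (named \code{lon_min,lon_max,lat_min,lat_max}).
#' @param cell_size_m cell edge length in metres (default 1000).
#' @return a \code{grid_geometry}.
#' @export
build_grid <- function(aoi, cell_size_m = 1000) {
  grid_geometry(aoi, cell_size_m)
}

parse_timestamp <- function(ts) {
  if (inherits(ts, "POSIXct")) return(ts)
  out <- as.POSIXct(ts, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(out)) out2 <- as.POSIXct(ts, tz = "UTC") else return(out)
  if (anyNA(out2)) stop("unparseable timestamps") else out2
}

#' Accumulate survey effort (seconds) per grid cell
#'
#' Consecutive track records form piecewise-linear segments; each segment's
#' duration is apportioned to the cells it crosses in proportion to the
#' length travelled in each. Records slower than \code{min_speed_kn}
#' (stationary vessel) are excluded, as are gaps longer than \code{max_gap_s}
#' (steaming between transects, overnight breaks).
#'
#' @param track data.frame with \code{timestamp}, \code{lon}, \code{lat},
#'   \code{speed_kn}.
#' @param geom the analysis \code{grid_geometry}.
#' @param min_speed_kn stationary threshold (knots).
#' @param max_gap_s maximum record gap treated as continuous effort (s);
#'   longer gaps (steaming between transects, overnight) contribute nothing.
#' @return numeric vector of seconds per cell (length = number of cells),
#'   with attribute \code{excluded_s} = seconds dropped as stationary,
#'   gap-broken or out-of-grid.
#' @export
accumulate_effort <- function(track, geom, min_speed_kn = 0.5, max_gap_s = 300) {
  t <- parse_timestamp(track$timestamp)
  if (any(diff(as.numeric(t)) <= 0)) stop("track timestamps must be strictly increasing")
  p <- project_lonlat(geom$proj, track$lon, track$lat)
  n <- length(t)
  effort <- numeric(n_cells(geom))
  excluded <- 0
  dt <- diff(as.numeric(t))
  for (i in seq_len(n - 1)) {
    if (dt[i] > max_gap_s) next  # off-effort gap: no time attributed
    spd <- min(track$speed_kn[i:(i + 1)])  # stationary at either end: excluded
    if (spd < min_speed_kn) { excluded <- excluded + dt[i]; next }
    parts <- split_segment(geom, p$x[i], p$y[i], p$x[i + 1], p$y[i + 1])
    for (j in seq_len(nrow(parts))) {
      cid <- parts$cell_id[j]
      sec <- parts$frac[j] * dt[i]
      if (is.na(cid)) excluded <- excluded + sec
      else effort[cid] <- effort[cid] + sec
    }
  }
  attr(effort, "excluded_s") <- excluded
  effort
}

# Split the segment (x1,y1)->(x2,y2) at cell boundaries.
# Returns data.frame(cell_id, frac) with frac summing to 1.
split_segment <- function(geom, x1, y1, x2, y2) {
  ts <- c(0, 1)
  for (axis in 1:2) {
    a1 <- if (axis == 1) x1 else y1
    a2 <- if (axis == 1) x2 else y2
    o <- if (axis == 1) geom$xmin else geom$ymin
    if (a1 != a2) {
      k <- (seq(floor((min(a1, a2) - o) / geom$cell_size),
                ceiling((max(a1, a2) - o) / geom$cell_size)))
      cross <- (o + k * geom$cell_size - a1) / (a2 - a1)
      ts <- c(ts, cross[cross > 0 & cross < 1])
    }
  }
  ts <- sort(unique(ts))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  data.frame(
    cell_id = cell_at_xy(geom, x1 + mid * (x2 - x1), y1 + mid * (y2 - y1)),
    frac = diff(ts)
  )
}

#' Assign sightings to grid cells with exclusion rules
#'
#' Each sighting is mapped to the cell containing the bird's first observed
#' location. A sighting is excluded when the vessel was travelling above
#' \code{max_speed_kn} at the time, or when the vessel's contiguous visit to
#' that cell exceeded \code{max_visit_min} minutes, or when the position
#' falls outside the grid. Exclusions are itemized.
#'
#' @param sightings data.frame with \code{timestamp}, \code{lon}, \code{lat},
#'   \code{count}.
#' @param track track data.frame (see [accumulate_effort()]).
#' @param geom the analysis \code{grid_geometry}.
#' @param max_speed_kn vessel-speed exclusion threshold (knots, default 17).
#' @param max_visit_min cell-visit duration exclusion threshold (minutes).
#' @return list with \code{counts} (birds per cell), \code{cells_with_birds},
#'   \code{included} (data.frame sighting row, cell_id) and
#'   \code{exclusions} (data.frame sighting row, reason).
#' @export
assign_sightings <- function(sightings, track, geom,
                             max_speed_kn = 17, max_visit_min = 15) {
  counts <- numeric(n_cells(geom))
  inc <- list(); exc <- list()
  if (nrow(sightings) == 0) {
    return(list(counts = counts, cells_with_birds = integer(0),
                included = data.frame(row = integer(0), cell_id = integer(0)),
                exclusions = data.frame(row = integer(0), reason = character(0))))
  }
  st <- as.numeric(parse_timestamp(sightings$timestamp))
  tt <- as.numeric(parse_timestamp(track$timestamp))
  tp <- project_lonlat(geom$proj, track$lon, track$lat)
  track_cell <- cell_at_xy(geom, tp$x, tp$y)
  for (i in seq_len(nrow(sightings))) {
    cid <- cell_at_lonlat(geom, sightings$lon[i], sightings$lat[i])
    if (is.na(cid)) { exc[[length(exc) + 1]] <- list(i, "outside_grid"); next }
    j <- which.min(abs(tt - st[i]))
    if (track$speed_kn[j] > max_speed_kn) {
      exc[[length(exc) + 1]] <- list(i, "vessel_speed"); next
    }
    if (visit_duration_s(tt, track_cell, cid, st[i]) > max_visit_min * 60) {
      exc[[length(exc) + 1]] <- list(i, "visit_duration"); next
    }
    counts[cid] <- counts[cid] + sightings$count[i]
    inc[[length(inc) + 1]] <- list(i, cid)
  }
  to_df <- function(lst, nm) {
    if (!length(lst)) {
      stats::setNames(data.frame(integer(0),
                                 if (nm[2] == "reason") character(0) else integer(0)), nm)
    } else {
      stats::setNames(data.frame(vapply(lst, function(e) e[[1]], numeric(1)),
                                 unlist(lapply(lst, function(e) e[[2]]))), nm)
    }
  }
  list(counts = counts, cells_with_birds = which(counts > 0),
       included = to_df(inc, c("row", "cell_id")),
       exclusions = to_df(exc, c("row", "reason")))
}

# Duration (s) of the contiguous run of track records in cell `cid`
# nearest to time `at`; gaps > 120 s break contiguity. One record = 60 s.
visit_duration_s <- function(track_time, track_cell, cid, at) {
  idx <- which(track_cell == cid & !is.na(track_cell))
  if (!length(idx)) return(0)
  runs <- split(idx, cumsum(c(TRUE, diff(idx) > 1 | diff(track_time[idx]) > 120)))
  near <- which.min(vapply(runs, function(r) min(abs(track_time[r] - at)), numeric(1)))
  r <- runs[[near]]
  (track_time[r[length(r)]] - track_time[r[1]]) + 60
}

#' Label cells presence / absence / undetermined
#'
#' A cell with birds is a presence regardless of effort. A zero-bird cell is
#' an absence only when the vessel spent at least \code{min_absence_s}
#' seconds in it; shorter visits are "undetermined" and excluded from model
#' fitting, reducing false absences.
#'
#' @param effort numeric seconds per cell (from [accumulate_effort()]).
#' @param counts numeric birds per cell (from [assign_sightings()]).
#' @param geom the analysis \code{grid_geometry}.
#' @param min_absence_s minimum effort for an absence label (default 180).
#' @return data.frame (one row per cell with any effort or birds):
#'   \code{cell_id}, \code{effort_s}, \code{n_birds}, \code{label}; with
#'   attribute \code{fraction_zero_removed}, the fraction of zero-sighting
#'   visited cells dropped as undetermined.
#' @export
label_cells <- function(effort, counts, geom, min_absence_s = 180) {
  if (any(effort < 0)) stop("negative effort")
  keep <- which(effort > 0 | counts > 0)
  lab <- ifelse(counts[keep] > 0, "presence",
                ifelse(effort[keep] >= min_absence_s, "absence", "undetermined"))
  out <- data.frame(cell_id = keep, effort_s = effort[keep],
                    n_birds = counts[keep],
                    label = factor(lab, levels = c("absence", "presence",
                                                   "undetermined")))
  zero <- out$n_birds == 0
  attr(out, "fraction_zero_removed") <-
    if (any(zero)) base::mean(out$label[zero] == "undetermined") else NA_real_
  out
}

#' Attach covariates to labelled cells
#'
#' Dynamic layers (SST, salinity, chlorophyll by default) are extracted at
#' cell centres by bilinear interpolation; static layers take the cell mean
#' (the cell value when the environment shares the analysis grid). Adds
#' centre latitude/longitude, optional great-circle distance to a coastline
#' polyline, the effort-weighted mean sea state from track records in the
#' cell, and optional per-species fish backscatter sums.
#'
#' @param cells data.frame from [label_cells()].
#' @param env an \code{env_stack}.
#' @param geom the analysis \code{grid_geometry}.
#' @param track optional track data.frame, needed for \code{sea_state}.
#' @param coastline optional two-column matrix (lon, lat) of an ordered
#'   coastline polyline; enables \code{distance_to_coast} (km).
#' @param fish optional data.frame \code{cell_id, species, nasc}; summed per
#'   cell and spread to one column per species.
#' @param dynamic_layers names of layers extracted bilinearly.
#' @return the cells data.frame with covariate columns appended.
#' @export
attach_covariates <- function(cells, env, geom, track = NULL, coastline = NULL,
                              fish = NULL,
                              dynamic_layers = c("sst", "salinity", "chlorophyll")) {
  cc <- cell_centres(geom)[cells$cell_id, ]
  cells$lon <- cc$lon; cells$lat <- cc$lat
  same <- same_geometry(env$geom, geom)
  for (nm in names(env$layers)) {
    r <- env$layers[[nm]]
    if (nm %in% dynamic_layers) {
      cells[[nm]] <- suppressWarnings(extract_bilinear(r, x = cc$x, y = cc$y))
    } else if (same) {
      cells[[nm]] <- r$values[cells$cell_id]
    } else {
      cells[[nm]] <- cell_mean_extract(r, geom, cells$cell_id)
    }
  }
  if (!is.null(coastline)) {
    cells$distance_to_coast <- distance_to_polyline_km(cc$lon, cc$lat, coastline)
  }
  if (!is.null(track)) {
    tc <- cell_at_lonlat(geom, track$lon, track$lat)
    ss <- tapply(track$sea_state, tc, base::mean)
    cells$sea_state <- as.numeric(ss[as.character(cells$cell_id)])
  }
  if (!is.null(fish)) {
    for (sp in unique(fish$species)) {
      f <- fish[fish$species == sp, ]
      s <- tapply(f$nasc, f$cell_id, sum)
      v <- rep(0, nrow(cells))
      m <- match(cells$cell_id, as.integer(names(s)))
      v[!is.na(m)] <- s[m[!is.na(m)]]
      cells[[sp]] <- v
    }
  }
  cells
}

# mean of env cells whose centres fall inside each analysis cell
cell_mean_extract <- function(r, geom, cell_ids) {
  ec <- cell_centres(r$geom)
  target <- cell_at_xy(geom, ec$x, ec$y)
  agg <- tapply(r$values, target, base::mean, na.rm = TRUE)
  out <- as.numeric(agg[as.character(cell_ids)])
  miss <- is.na(out)
  if (any(miss)) {
    cc <- cell_centres(geom)[cell_ids[miss], ]
    out[miss] <- suppressWarnings(extract_bilinear(r, x = cc$x, y = cc$y))
  }
  out
}

#' Great-circle distance from points to a coastline polyline (km)
#'
#' The polyline is densified to ~250 m vertex spacing and the minimum
#' haversine point-to-vertex distance is reported.
#'
#' @param lon,lat query points (degrees).
#' @param coastline two-column matrix (lon, lat) of ordered vertices.
#' @export
distance_to_polyline_km <- function(lon, lat, coastline) {
  cl <- as.matrix(coastline)
  dense <- list(cl[1, , drop = FALSE])
  for (i in seq_len(nrow(cl) - 1)) {
    d <- geosphere::distHaversine(cl[i, ], cl[i + 1, ])
    k <- max(1, ceiling(d / 50))
    f <- seq(0, 1, length.out = k + 1)[-1]
    dense[[i + 1]] <- cbind(cl[i, 1] + f * (cl[i + 1, 1] - cl[i, 1]),
                            cl[i, 2] + f * (cl[i + 1, 2] - cl[i, 2]))
  }
  verts <- do.call(rbind, dense)
  vapply(seq_along(lon), function(i) {
    min(geosphere::distHaversine(c(lon[i], lat[i]), verts)) / 1000
  }, numeric(1))
}

# ---- prediction area ----------------------------------------------------

#' Build the prediction area polygon
#'
#' Minimum convex polygon of the supplied visited cell centres, intersected
#' with the area-of-interest rectangle. Environmental coverage is enforced
#' downstream (cells lacking covariates predict to missing). Area is
#' computed in the metric projection.
#'
#' @param cells data.frame of visited cells with \code{cell_id} (typically
#'   the survey years that bound the area, excluding design-change years).
#' @param geom the analysis \code{grid_geometry}.
#' @return object of class \code{prediction_area}: \code{polygon} (matrix of
#'   metric x,y vertices, counter-clockwise), \code{area_km2}, \code{geom}.
#' @export
build_prediction_area <- function(cells, geom) {
  cc <- cell_centres(geom)[unique(cells$cell_id), ]
  if (nrow(cc) < 3) stop("need at least 3 visited cells")
  h <- grDevices::chull(cc$x, cc$y)
  poly <- cbind(x = cc$x[h], y = cc$y[h])
  if (abs(polygon_area(poly)) < 1e-6) stop("degenerate hull: collinear cell centres")
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  rect <- c(geom$xmin, geom$ymin,
            geom$xmin + geom$nx * geom$cell_size,
            geom$ymin + geom$ny * geom$cell_size)
  poly <- clip_polygon_rect(poly, rect)
  structure(list(polygon = poly, area_km2 = polygon_area(poly) / 1e6,
                 geom = geom), class = "prediction_area")
}

#' @export
print.prediction_area <- function(x, ...) {
  cat(sprintf("prediction_area: %d vertices, %.1f km2\n",
              nrow(x$polygon), x$area_km2))
  invisible(x)
}

# signed shoelace area (positive = counter-clockwise)
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

# Sutherland-Hodgman clip of a convex/simple polygon to a rectangle
clip_polygon_rect <- function(poly, rect) {
  inside_fun <- list(
    function(p) p[1] >= rect[1], function(p) p[2] >= rect[2],
    function(p) p[1] <= rect[3], function(p) p[2] <= rect[4]
  )
  intersect_fun <- list(
    function(a, b) a + (b - a) * (rect[1] - a[1]) / (b[1] - a[1]),
    function(a, b) a + (b - a) * (rect[2] - a[2]) / (b[2] - a[2]),
    function(a, b) a + (b - a) * (rect[3] - a[1]) / (b[1] - a[1]),
    function(a, b) a + (b - a) * (rect[4] - a[2]) / (b[2] - a[2])
  )
  out <- poly
  for (e in 1:4) {
    if (nrow(out) == 0) break
    inp <- out; out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    for (i in seq_len(n)) {
      cur <- inp[i, ]; prev <- inp[if (i == 1) n else i - 1, ]
      ci <- inside_fun[[e]](cur); pi_ <- inside_fun[[e]](prev)
      if (ci) {
        if (!pi_) out <- rbind(out, intersect_fun[[e]](prev, cur))
        out <- rbind(out, cur)
      } else if (pi_) {
        out <- rbind(out, intersect_fun[[e]](prev, cur))
      }
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Are points inside the prediction area?
#' @param area a \code{prediction_area}.
#' @param x,y metric coordinates.
#' @return logical vector (ray-casting; boundary points count as inside).
#' @export
point_in_area <- function(area, x, y) {
  poly <- area$polygon
  n <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  # boundary tolerance: points within half a metre of an edge count inside
  inside | on_polygon_edge(poly, x, y, tol = 0.5)
}

on_polygon_edge <- function(poly, x, y, tol = 0.5) {
  n <- nrow(poly)
  hit <- rep(FALSE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ax <- poly[i, 1]; ay <- poly[i, 2]; bx <- poly[j, 1]; by <- poly[j, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- pmin(1, pmax(0, ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / len2))
    d2 <- (x - (ax + t * (bx - ax)))^2 + (y - (ay + t * (by - ay)))^2
    hit <- hit | d2 <= tol^2
  }
  hit
}
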