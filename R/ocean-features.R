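# Derived bathymetric and tidal covariates.
#
# Bathymetry is stored as elevation (negative below sea level), so a
# positive depth-anomaly residual literally means "shallower than expected".
# The stratification index uses the water-column depth h = -elevation.

#' Environment stack: co-registered raster layers
#'
#' Bundles named \code{grid_raster} layers sharing one \code{grid_geometry}.
#' Canonical layer names: \code{depth} (elevation, m, negative below sea
#' level), \code{sst} (deg C), \code{salinity} (PSU), \code{chlorophyll}
#' (mg/m3), \code{max_current} (m/s), and the derived \code{roughness},
#' \code{aspect}, \code{anomaly}, \code{strat_index}.
#'
#' @param geom a \code{grid_geometry}.
#' @param layers named list of \code{grid_raster} objects or numeric vectors.
#' @return an object of class \code{env_stack}.
#' @export
env_stack <- function(geom, layers = list()) {
  out <- structure(list(geom = geom, layers = list()), class = "env_stack")
  for (nm in names(layers)) out <- stack_set(out, nm, layers[[nm]])
  out
}

stack_set <- function(stack, name, layer) {
  if (is.numeric(layer)) layer <- grid_raster(stack$geom, layer, name)
  stop_if_geometry_mismatch(list(geom = stack$geom), layer)
  layer$name <- name
  stack$layers[[name]] <- layer
  stack
}

#' Get a layer from an [env_stack()]
#' @param stack an \code{env_stack}.
#' @param name layer name.
#' @export
stack_layer <- function(stack, name) {
  if (!name %in% names(stack$layers)) {
    stop("layer '", name, "' not in stack (has: ",
         paste(names(stack$layers), collapse = ", "), ")")
  }
  stack$layers[[name]]
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d x %d cells; layers: %s\n", x$geom$nx, x$geom$ny,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# neighbour offsets of the 8-cell Moore neighbourhood
.MOORE <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
                dy = c(-1, -1, -1, 0, 0, 1, 1, 1))

#' Terrain ruggedness index (TRI)
#'
#' Mean absolute difference between each cell and its eight neighbours;
#' edge cells use the neighbours that exist (no padding). Identifies
#' bathymetric features with abrupt depth changes.
#'
#' @param depth a \code{grid_raster} of elevation (any additive offset
#'   cancels; TRI is shift-invariant).
#' @return a \code{grid_raster} named \code{"roughness"}, in metres.
#' @export
terrain_ruggedness <- function(depth) {
  g <- depth$geom
  if (g$nx < 2 || g$ny < 2) stop("raster smaller than 2x2")
  m <- raster_matrix(depth)
  acc <- matrix(0, g$ny, g$nx)
  cnt <- matrix(0L, g$ny, g$nx)
  for (k in seq_len(nrow(.MOORE))) {
    sh <- shift_matrix(m, .MOORE[k, "dx"], .MOORE[k, "dy"])
    d <- abs(m - sh)
    ok <- !is.na(d)
    acc[ok] <- acc[ok] + d[ok]
    cnt <- cnt + ok
  }
  out <- ifelse(cnt > 0, acc / cnt, NA_real_)
  out[is.na(m)] <- NA_real_
  raster_from_matrix(g, out, "roughness")
}

# value of the neighbour at offset (dx east, dy north) for every cell;
# NA where the neighbour falls off the grid (row 1 = southernmost)
shift_matrix <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

#' Seafloor aspect (predominant downslope direction)
#'
#' Direction of steepest descent of the elevation surface, in degrees
#' clockwise from north. Interior gradients use Horn's 3x3 weighting; edges
#' fall back to one-sided differences over available neighbours. Flat cells
#' (zero gradient) are missing.
#'
#' @param depth a \code{grid_raster} of elevation.
#' @return a \code{grid_raster} named \code{"aspect"}, degrees in [0, 360).
#' @export
slope_aspect <- function(depth) {
  g <- depth$geom
  if (g$nx < 2 || g$ny < 2) stop("raster smaller than 2x2")
  m <- raster_matrix(depth)
  e <- shift_matrix(m, 1, 0);  w <- shift_matrix(m, -1, 0)
  n <- shift_matrix(m, 0, 1);  s <- shift_matrix(m, 0, -1)
  ne <- shift_matrix(m, 1, 1); nw <- shift_matrix(m, -1, 1)
  se <- shift_matrix(m, 1, -1); sw <- shift_matrix(m, -1, -1)
  cs <- g$cell_size
  horn_x <- ((ne + 2 * e + se) - (nw + 2 * w + sw)) / (8 * cs)
  horn_y <- ((ne + 2 * n + nw) - (se + 2 * s + sw)) / (8 * cs)
  # one-sided / central fallback where the full 3x3 block is unavailable
  fx <- one_sided_grad(m, e, w, cs)
  fy <- one_sided_grad(m, n, s, cs)
  dzdx <- ifelse(is.na(horn_x), fx, horn_x)
  dzdy <- ifelse(is.na(horn_y), fy, horn_y)
  asp <- (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  flat <- !is.na(dzdx) & !is.na(dzdy) & dzdx == 0 & dzdy == 0
  asp[flat] <- NA_real_
  asp[is.na(m)] <- NA_real_
  raster_from_matrix(g, asp, "aspect")
}

one_sided_grad <- function(m, plus, minus, cs) {
  ifelse(!is.na(plus) & !is.na(minus), (plus - minus) / (2 * cs),
         ifelse(!is.na(plus), (plus - m) / cs,
                ifelse(!is.na(minus), (m - minus) / cs, NA_real_)))
}

#' Seafloor depth anomaly
#'
#' Residuals of a penalized two-dimensional smooth of elevation over
#' coordinates (Gaussian GAM), capturing features unusually shallow or deep
#' for their location. Positive residuals = shallower than expected.
#'
#' @param depth a \code{grid_raster} of elevation.
#' @param k basis dimension of the two-dimensional thin-plate smooth;
#'   generous by default (penalization controls effective complexity).
#' @return a \code{grid_raster} named \code{"anomaly"}, metres.
#' @export
depth_anomaly <- function(depth, k = 60) {
  v <- depth$values
  ok <- is.finite(v)
  if (sum(ok) < 50) stop("need at least 50 non-missing cells")
  cc <- cell_centres(depth$geom)
  dat <- data.frame(z = v[ok], x = cc$x[ok], y = cc$y[ok])
  k <- min(k, sum(ok) - 1)
  fit <- mgcv::gam(z ~ s(x, y, k = k), data = dat, method = "REML")
  out <- rep(NA_real_, length(v))
  out[ok] <- stats::residuals(fit)
  r <- grid_raster(depth$geom, out, "anomaly")
  attr(r, "fitted") <- stats::fitted(fit)
  r
}

#' Simpson-Hunter stratification index
#'
#' \code{log10(h / u^3)} with water depth \code{h} (m, positive) and maximum
#' depth-averaged current speed \code{u} (m/s). Low values indicate tidally
#' mixed water, high values stratified water; tidal fronts sit near 1.9.
#' Missing wherever \code{h <= 0} (land) or \code{u <= 0}.
#'
#' @param depth elevation raster (negative below sea level); \code{h = -depth}.
#' @param max_current current-speed raster (m/s), co-registered with depth.
#' @return a \code{grid_raster} named \code{"strat_index"} (log10 m^-2 s^3).
#' @export
stratification_index <- function(depth, max_current) {
  stop_if_geometry_mismatch(depth, max_current)
  h <- -depth$values
  u <- max_current$values
  si <- rep(NA_real_, length(h))
  ok <- is.finite(h) & is.finite(u) & h > 0 & u > 0
  si[ok] <- log10(h[ok] / u[ok]^3)
  grid_raster(depth$geom, si, "strat_index")
}

#' Classify water column from the stratification index
#'
#' Three-way classification around the front value 1.9: \code{front} within
#' \code{tolerance} of 1.9, otherwise \code{mixed} below and
#' \code{stratified} above.
#'
#' @param si numeric stratification-index values (log10 m^-2 s^3).
#' @param front_value index value at tidal fronts (1.9).
#' @param tolerance half-width of the front band.
#' @return factor with levels mixed, front, stratified (\code{NA} in, \code{NA} out).
#' @export
classify_stratification <- function(si, front_value = 1.9, tolerance = 0.1) {
  out <- rep(NA_character_, length(si))
  fin <- is.finite(si)
  front <- fin & abs(si - front_value) <= tolerance
  out[front] <- "front"
  out[fin & !front & si < front_value] <- "mixed"
  out[fin & !front & si >= front_value] <- "stratified"
  factor(out, levels = c("mixed", "front", "stratified"))
}

#' Derive all bathymetric and tidal covariates in one call
#'
#' Adds \code{roughness}, \code{aspect}, \code{anomaly} and
#' \code{strat_index} to a stack that has \code{depth} and
#' \code{max_current}.
#'
#' @param stack an \code{env_stack} with at least \code{depth}; the
#'   stratification index additionally needs \code{max_current}.
#' @param anomaly_k basis dimension passed to [depth_anomaly()].
#' @param layers which derived layers to compute.
#' @return the stack with derived layers attached.
#' @export
derive_features <- function(stack, anomaly_k = 60,
                            layers = c("roughness", "aspect", "anomaly",
                                       "strat_index")) {
  depth <- stack_layer(stack, "depth")
  if ("roughness" %in% layers) {
    stack <- stack_set(stack, "roughness", terrain_ruggedness(depth))
  }
  if ("aspect" %in% layers) {
    stack <- stack_set(stack, "aspect", slope_aspect(depth))
  }
  if ("anomaly" %in% layers) {
    stack <- stack_set(stack, "anomaly", depth_anomaly(depth, k = anomaly_k))
  }
  if ("strat_index" %in% layers && "max_current" %in% names(stack$layers)) {
    stack <- stack_set(stack, "strat_index",
                       stratification_index(depth, stack_layer(stack, "max_current")))
  }
  stack
}
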