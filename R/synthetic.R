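# Synthetic at-sea surveys with a known habitat-suitability surface.
#
# Everything is driven by one scenario seed; each (seed, year, purpose)
# triple gets its own random stream so adding a generator never perturbs
# draws made by existing ones.

#' Scenario configuration for a synthetic survey
#'
#' Defaults describe the study conditions the pipeline targets: the western
#' English Channel / southern Celtic Sea area of interest, a 1-km analysis
#' grid, five annual October surveys along parallel transects run at about
#' 10 knots, and sparse sightings (about 2\% of effort cells occupied).
#'
#' @param seed integer; fixes all randomness end-to-end.
#' @param extent lon/lat bounding box (degrees), named
#'   \code{lon_min,lon_max,lat_min,lat_max}.
#' @param cell_size grid cell edge (m).
#' @param n_years number of annual surveys.
#' @param transect_spacing_km spacing of parallel north-south transects (km).
#' @param vessel_speed_kn survey speed (knots).
#' @param suitability_coefficients named coefficients of the true logistic
#'   suitability surface, on standardized covariates; the special name
#'   \code{front_bump} adds a Gaussian bump centred on stratification-index
#'   value 1.9 so suitability peaks at tidal fronts.
#' @param detection_prob per-cell-visit detection probability in [0,1].
#' @param field_smoothness correlation length of the synthetic environmental
#'   fields (km); \code{Inf} gives spatially constant layers.
#' @param prevalence_target fraction of effort cells with presence; the
#'   suitability intercept is calibrated so that the expected prevalence
#'   equals this value.
#' @param flock_mean if > 1, sighting counts are drawn from a zero-truncated
#'   geometric distribution with this mean; default 1 (single birds).
#' @param base_year calendar year of survey 1.
#' @return a list of class \code{scenario_config}.
#' @export
scenario_config <- function(seed = 1,
                            extent = c(lon_min = -6.888, lon_max = -2.003,
                                       lat_min = 49.491, lat_max = 51.622),
                            cell_size = 1000,
                            n_years = 5,
                            transect_spacing_km = 15,
                            vessel_speed_kn = 10,
                            suitability_coefficients = c(strat_index = 0.7,
                                                         sst = -0.8,
                                                         front_bump = 1.8),
                            detection_prob = 1,
                            field_smoothness = 25,
                            prevalence_target = 0.022,
                            flock_mean = 1,
                            base_year = 2013) {
  extent <- unlist(extent)  # tolerate YAML-style lists
  suitability_coefficients <- unlist(suitability_coefficients)
  if (detection_prob < 0 || detection_prob > 1) stop("detection_prob must be in [0,1]")
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("prevalence_target must be in (0,1)")
  }
  check_extent(extent)
  structure(list(seed = as.integer(seed), extent = extent,
                 cell_size = cell_size, n_years = n_years,
                 transect_spacing_km = transect_spacing_km,
                 vessel_speed_kn = vessel_speed_kn,
                 suitability_coefficients = suitability_coefficients,
                 detection_prob = detection_prob,
                 field_smoothness = field_smoothness,
                 prevalence_target = prevalence_target,
                 flock_mean = flock_mean, base_year = base_year),
            class = "scenario_config")
}

#' Derive a reproducible sub-seed for a (seed, year, purpose) stream
#' @param seed scenario seed.
#' @param year year index (0 for static layers).
#' @param purpose short label naming the generator.
#' @return a 32-bit integer seed.
#' @export
derive_seed <- function(seed, year, purpose) {
  cp <- utf8ToInt(purpose)
  h <- sum(cp * seq_along(cp)) %% 1000003
  as.integer((as.numeric(seed) * 48611 + year * 7919 + h * 104729) %% 2147483629)
}

# Evaluate expr under a derived stream, restoring the caller's RNG state.
with_stream <- function(seed, year, purpose, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(derive_seed(seed, year, purpose))
  force(expr)
}

#' Smooth Gaussian random field on a grid
#'
#' White noise convolved with a Gaussian kernel, giving (approximately)
#' a Gaussian correlation function \code{exp(-d^2 / (2 L^2))} with
#' correlation length \code{L}. The noise is generated on a padded grid so
#' the smoothing has no edge artefacts, then standardized to the requested
#' mean and standard deviation. Infinite correlation length gives a
#' constant field equal to \code{mean}.
#'
#' @param geom a \code{grid_geometry}.
#' @param corr_length_m correlation length in metres.
#' @param mean,sd moments of the returned field.
#' @param name layer name.
#' @return a \code{grid_raster}. Seed the RNG before calling.
#' @export
gaussian_field <- function(geom, corr_length_m, mean = 0, sd = 1, name = "field") {
  if (!is.finite(corr_length_m)) {
    return(grid_raster(geom, mean, name))
  }
  if (corr_length_m <= 0) stop("correlation length must be positive")
  # kernel sd chosen so the field covariance scale equals corr_length
  s <- corr_length_m / geom$cell_size / sqrt(2)
  half <- max(1L, ceiling(3 * s))
  kern <- stats::dnorm(seq(-half, half), sd = s)
  kern <- kern / sum(kern)
  pad <- half
  ny <- geom$ny + 2 * pad; nx <- geom$nx + 2 * pad
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  z <- apply(z, 2, function(col) smooth_1d(col, kern))
  z <- t(apply(z, 1, function(row) smooth_1d(row, kern)))
  z <- z[(pad + 1):(pad + geom$ny), (pad + 1):(pad + geom$nx), drop = FALSE]
  z <- (z - base::mean(z)) / stats::sd(z) * sd + mean
  raster_from_matrix(geom, z, name)
}

smooth_1d <- function(v, kern) {
  half <- (length(kern) - 1) / 2
  out <- stats::filter(c(rep(v[1], half), v, rep(v[length(v)], half)), kern, sides = 2)
  as.numeric(out[(half + 1):(half + length(v))])
}

#' Generate the synthetic environment stack for one survey year
#'
#' Produces spatially smooth bathymetry (elevation, negative below sea
#' level), maximum depth-averaged current speed, sea surface temperature,
#' salinity and chlorophyll on the scenario grid, and derives the
#' bathymetric/tidal covariates. Static fields (depth, current and their
#' derivatives) are identical across years; dynamic fields (SST, salinity,
#' chlorophyll) get a fresh realization per year.
#'
#' @param config a [scenario_config()].
#' @param year year index (1-based).
#' @param derive if \code{TRUE} (default) attach roughness, aspect, anomaly
#'   and stratification index via [derive_features()].
#' @param anomaly_k basis dimension for the depth-anomaly smooth.
#' @param derive_layers which derived layers to compute (passed to
#'   [derive_features()]).
#' @return an \code{env_stack}.
#' @export
generate_env_stack <- function(config, year = 1, derive = TRUE, anomaly_k = 60,
                               derive_layers = c("roughness", "aspect",
                                                 "anomaly", "strat_index")) {
  geom <- grid_geometry(config$extent, config$cell_size)
  L <- config$field_smoothness * 1000
  # static layers: stream independent of year
  depth <- with_stream(config$seed, 0, "depth", {
    f <- gaussian_field(geom, L, mean = 0, sd = 1)
    grid_raster(geom, -pmax(5, 70 + 30 * f$values), "depth")
  })
  max_current <- with_stream(config$seed, 0, "max_current", {
    f <- gaussian_field(geom, L, mean = 0, sd = 1)
    grid_raster(geom, pmax(0.05, 0.8 + 0.45 * f$values), "max_current")
  })
  sst <- with_stream(config$seed, year, "sst",
                     gaussian_field(geom, L, mean = 14, sd = 1.2, name = "sst"))
  salinity <- with_stream(config$seed, year, "salinity",
                          gaussian_field(geom, L, mean = 35, sd = 0.4, name = "salinity"))
  chl <- with_stream(config$seed, year, "chlorophyll", {
    f <- gaussian_field(geom, L, mean = 0.3, sd = 0.5)
    grid_raster(geom, exp(f$values), "chlorophyll")
  })
  stack <- env_stack(geom, list(depth = depth, max_current = max_current,
                                sst = sst, salinity = salinity,
                                chlorophyll = chl))
  if (derive) stack <- derive_features(stack, anomaly_k = anomaly_k,
                                       layers = derive_layers)
  stack
}

#' Add synthetic fish-backscatter layers to a stack
#'
#' Smooth strictly positive fields, generated independently of the bird
#' suitability surface — pure noise with respect to bird presence, which is
#' what the variable-importance experiments require.
#'
#' @param config a [scenario_config()].
#' @param stack an \code{env_stack} to extend.
#' @param year year index.
#' @param species character vector of species layer names.
#' @param smoothness_km correlation length of the fish fields (km);
#'   \code{NULL} reuses the scenario's field smoothness, \code{0} gives
#'   cellwise white noise. Variable-importance experiments want white
#'   noise: spatially autocorrelated "noise" fields are spuriously
#'   correlated with any spatial presence pattern in finite samples, which
#'   is a property of the data, not of the importance machinery under test.
#' @return the stack with one NASC-like layer per species.
#' @export
generate_fish_fields <- function(config, stack, year = 1,
                                 species = c("mackerel", "sprat", "anchovy",
                                             "sardine", "horse_mackerel",
                                             "herring", "boarfish"),
                                 smoothness_km = NULL) {
  L <- if (is.null(smoothness_km)) config$field_smoothness else smoothness_km
  L <- L * 1000
  for (sp in species) {
    layer <- with_stream(config$seed, year, paste0("fish_", sp), {
      v <- if (L <= 0) {
        stats::rnorm(n_cells(stack$geom), 2, 1)
      } else {
        gaussian_field(stack$geom, L, mean = 2, sd = 1)$values
      }
      grid_raster(stack$geom, exp(v), sp)
    })
    stack <- stack_set(stack, sp, layer)
  }
  stack
}

#' True habitat-suitability surface
#'
#' Logistic transform of a linear function of standardized covariates plus
#' an optional Gaussian "front bump" centred on stratification-index value
#' 1.9, so that suitability can peak at tidal fronts. Coefficient names must
#' be layer names of \code{env}, plus the special names \code{intercept} and
#' \code{front_bump}.
#'
#' @param env an \code{env_stack} holding every named covariate.
#' @param coefficients named numeric coefficients.
#' @param front_value,front_width centre and width of the front bump on the
#'   raw stratification-index scale.
#' @return a probability \code{grid_raster} (values in (0,1)).
#' @export
true_suitability <- function(env, coefficients, front_value = 1.9,
                             front_width = 0.15) {
  eta <- rep(0, n_cells(env$geom))
  for (nm in names(coefficients)) {
    b <- coefficients[[nm]]
    if (nm == "intercept") {
      eta <- eta + b
    } else if (nm == "front_bump") {
      if (!"strat_index" %in% names(env$layers)) {
        stop("front_bump requires a strat_index layer")
      }
      si <- stack_layer(env, "strat_index")$values
      bump <- exp(-(si - front_value)^2 / (2 * front_width^2))
      bump[!is.finite(bump)] <- 0
      eta <- eta + b * bump
    } else {
      if (!nm %in% names(env$layers)) {
        stop("coefficient '", nm, "' names a covariate missing from the stack")
      }
      v <- stack_layer(env, nm)$values
      z <- (v - base::mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      z[!is.finite(z)] <- 0
      eta <- eta + b * z
    }
  }
  grid_raster(env$geom, stats::plogis(eta), "suitability")
}

#' Build the scenario's ground truth, calibrating prevalence
#'
#' Evaluates the configured suitability surface and solves for the logistic
#' intercept such that mean(suitability) x detection_prob over the grid
#' equals the configured prevalence target. The generating coefficients are
#' kept on the object so recovery experiments can compare against them; the
#' modelling modules never see them.
#'
#' @param config a [scenario_config()].
#' @param env the year-1 \code{env_stack} (static layers drive the truth).
#' @return an object of class \code{synthetic_truth} with elements
#'   \code{suitability} (raster), \code{coefficients} (including the solved
#'   intercept) and \code{true_density} (birds/km^2 raster).
#' @export
synthetic_truth <- function(config, env) {
  coefs <- config$suitability_coefficients
  coefs <- coefs[names(coefs) != "intercept"]
  target <- config$prevalence_target / max(config$detection_prob, 1e-12)
  if (target >= 1) stop("prevalence_target / detection_prob must be < 1")
  base_suit <- true_suitability(env, coefs)
  eta0 <- stats::qlogis(base_suit$values)
  ok <- is.finite(eta0)
  f <- function(b0) base::mean(stats::plogis(eta0[ok] + b0)) - target
  b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  suit <- grid_raster(env$geom, stats::plogis(eta0 + b0), "suitability")
  structure(list(
    suitability = suit,
    coefficients = c(intercept = b0, coefs),
    prevalence = target,
    true_density = grid_raster(env$geom, suit$values * config$flock_mean,
                               "true_density")
  ), class = "synthetic_truth")
}

#' Re-evaluate the truth surface on another year's environment
#'
#' The generating slope coefficients are fixed properties of the scenario;
#' the suitability surface itself tracks each year's dynamic fields, so
#' presence probability responds to year-to-year environmental variation.
#' The intercept is re-solved each year to hold the configured prevalence:
#' with strong coefficients the mean of the logistic surface is dominated
#' by that year's field extremes, so a frozen intercept would let
#' prevalence swing by an order of magnitude between realizations. A
#' year-varying baseline with fixed habitat response is also what the
#' interannual abundance variation of a real population looks like.
#'
#' @param truth a [synthetic_truth()] object.
#' @param env the year's \code{env_stack}.
#' @return the truth object with \code{suitability} and \code{true_density}
#'   re-evaluated on \code{env}.
#' @export
truth_for_year <- function(truth, env) {
  coefs <- truth$coefficients
  base_suit <- true_suitability(env, coefs[names(coefs) != "intercept"])
  eta0 <- stats::qlogis(base_suit$values)
  ok <- is.finite(eta0)
  f <- function(b0) base::mean(stats::plogis(eta0[ok] + b0)) - truth$prevalence
  b0 <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  suit <- grid_raster(env$geom, stats::plogis(eta0 + b0), "suitability")
  truth$suitability <- suit
  truth$true_density <- grid_raster(env$geom, suit$values, "true_density")
  truth
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: mean suitability",
      signif(base::mean(x$suitability$values, na.rm = TRUE), 3),
      "\n  coefficients:", paste(names(x$coefficients),
                                 signif(x$coefficients, 3),
                                 sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Simulate one annual survey: vessel track and sightings
#'
#' The vessel runs parallel north-south transects boustrophedon at the
#' configured speed, with one track record per minute (position, speed, and
#' a Beaufort sea state following an integer autoregressive walk clamped to
#' 0-8). Survey days run 08:00-18:00 UTC. Sightings are drawn one per
#' cell-visit as Bernoulli(suitability x detection_prob), placed on the
#' track within the visit, with perpendicular distance uniform on
#' [0, 1000] m and a flying/on-water behaviour flag.
#'
#' @param config a [scenario_config()].
#' @param env the year's \code{env_stack} (supplies the grid).
#' @param truth a [synthetic_truth()] object.
#' @param year year index (1-based).
#' @return list with data.frames \code{track} (timestamp, lon, lat,
#'   speed_kn, sea_state) and \code{sightings} (timestamp, lon, lat, count,
#'   perp_distance_m, behaviour).
#' @export
simulate_survey <- function(config, env, truth, year = 1) {
  geom <- env$geom
  stopifnot(same_geometry(geom, truth$suitability$geom))
  spacing <- config$transect_spacing_km * 1000
  width <- geom$nx * geom$cell_size
  height <- geom$ny * geom$cell_size
  if (geom$xmin + spacing / 2 > geom$xmin + width) {
    stop("no transects fit inside the extent")
  }
  xs <- seq(geom$xmin + spacing / 2, geom$xmin + width - 1, by = spacing)
  speed_ms <- config$vessel_speed_kn * 1852 / 3600
  step <- speed_ms * 60  # metres per minute

  with_stream(config$seed, year, "survey", {
    # per-minute positions along boustrophedon transects
    pts_x <- numeric(0); pts_y <- numeric(0); leg_id <- integer(0)
    for (k in seq_along(xs)) {
      n_steps <- floor(height / step)
      ys <- geom$ymin + (0:n_steps) * step
      if (k %% 2 == 0) ys <- rev(ys)
      pts_x <- c(pts_x, rep(xs[k], length(ys)))
      pts_y <- c(pts_y, ys)
      leg_id <- c(leg_id, rep(k, length(ys)))
    }
    n <- length(pts_x)
    # timestamps: one record per minute on-transect; gaps between transects
    # and overnight breaks carry no records
    day_len_s <- 10 * 3600
    start <- as.POSIXct(sprintf("%d-10-01 08:00:00", config$base_year + year - 1),
                        tz = "UTC")
    t_s <- numeric(n)
    cur <- 0; day <- 0
    for (i in seq_len(n)) {
      if (i > 1) {
        cur <- cur + ifelse(leg_id[i] != leg_id[i - 1],
                            60 * ceiling(spacing / step) + 180, 60)
      }
      if (cur >= day_len_s) { day <- day + 1; cur <- 0 }
      t_s[i] <- day * 86400 + cur
    }
    timestamp <- start + t_s
    # Beaufort sea state: clamped integer AR walk
    ss <- integer(n)
    ss[1] <- sample(1:4, 1)
    stepdraw <- sample(c(-1L, 0L, 1L), n, replace = TRUE,
                       prob = c(0.05, 0.9, 0.05))
    for (i in 2:n) ss[i] <- min(8L, max(0L, ss[i - 1] + stepdraw[i]))
    ll <- unproject_xy(geom$proj, pts_x, pts_y)
    track <- data.frame(
      timestamp = format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      lon = ll$lon, lat = ll$lat,
      speed_kn = config$vessel_speed_kn,
      sea_state = ss
    )
    # sightings: one Bernoulli draw per contiguous cell-visit
    cells <- cell_at_xy(geom, pts_x, pts_y)
    visit <- cumsum(c(TRUE, cells[-1] != cells[-n] | leg_id[-1] != leg_id[-n]))
    sight <- list()
    for (v in split(seq_len(n), visit)) {
      cid <- cells[v[1]]
      if (is.na(cid)) next
      p <- truth$suitability$values[cid] * config$detection_prob
      if (!is.finite(p)) next
      if (stats::runif(1) < p) {
        i <- if (length(v) > 1) sample(v, 1) else v
        cnt <- if (config$flock_mean > 1) {
          1L + stats::rgeom(1, 1 / config$flock_mean)
        } else 1L
        sight[[length(sight) + 1]] <- data.frame(
          timestamp = track$timestamp[i],
          lon = track$lon[i], lat = track$lat[i],
          count = cnt,
          perp_distance_m = stats::runif(1, 0, 1000),
          behaviour = if (stats::runif(1) < 0.8) "flying" else "on_water"
        )
      }
    }
    sightings <- if (length(sight)) do.call(rbind, sight) else
      data.frame(timestamp = character(0), lon = numeric(0), lat = numeric(0),
                 count = integer(0), perp_distance_m = numeric(0),
                 behaviour = character(0))
    list(track = track, sightings = sightings)
  })
}

#' Simulate a strip-transect survey over a homogeneous bird field
#'
#' Daily counts are Poisson with mean \code{density x distance x width} —
#' the idealized sampling model under which the density-multiplication
#' abundance estimator is unbiased. Used for estimator-calibration
#' experiments.
#'
#' @param true_density birds per km^2, spatially homogeneous.
#' @param daily_distance_km numeric vector of per-day transect distances.
#' @param strip_width_km strip width (km).
#' @param start_date date of the first survey day.
#' @return data.frame with \code{date}, \code{distance_km},
#'   \code{birds_within_300m}.
#' @export
simulate_strip_survey <- function(true_density, daily_distance_km,
                                  strip_width_km, start_date = as.Date("2013-10-01")) {
  birds <- stats::rpois(length(daily_distance_km),
                        true_density * daily_distance_km * strip_width_km)
  data.frame(date = start_date + seq_along(daily_distance_km) - 1,
             distance_km = daily_distance_km,
             birds_within_300m = birds)
}
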