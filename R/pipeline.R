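# Run configuration and end-to-end orchestration of a synthetic survey
# analysis: simulate -> features -> grid -> GAM -> RF -> abundance.

#' Run configuration
#'
#' Collects every tunable of the pipeline with the study's constants as
#' defaults: the 180-s false-absence filter, the 17-kn and 15-min sighting
#' exclusions, basis dimension 4, 500 trees on 66\% subsamples, the
#' square-root mtry multipliers, the 1.9 front value, and the 30,600 global
#' population. Round-trips losslessly through YAML.
#'
#' @param ... overrides of the defaults, nested as in the returned list.
#' @param file optional YAML file of overrides.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- list(
    scenario = list(seed = 1, n_years = 5, transect_spacing_km = 15,
                    vessel_speed_kn = 10, detection_prob = 1,
                    field_smoothness = 25, prevalence_target = 0.022,
                    cell_size = 1000),
    filters = list(min_absence_s = 180, max_speed_kn = 17,
                   max_visit_min = 15, min_speed_kn = 0.5),
    model = list(k = 4, n_trees = 500, sample_frac = 0.66, mtry = 4,
                 mtry_multipliers = c(0.5, 1, 2), cv_folds = 10,
                 gam_pool = "reduced"),
    constants = list(area_km2 = NA, global_population = 30600,
                     front_value = 1.9)
  )
  apply_over <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(over[[nm]]) && is.list(base[[nm]])) {
        apply_over(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  if (!is.null(file)) cfg <- apply_over(cfg, yaml::read_yaml(file))
  cfg <- apply_over(cfg, list(...))
  stopifnot(cfg$filters$min_absence_s > 0, cfg$filters$max_speed_kn > 0,
            cfg$filters$max_visit_min > 0, cfg$scenario$n_years >= 1)
  structure(cfg, class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# FNV-1a hash of a string, hex; used for the run manifest
fnv1a <- function(txt) {
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build the labelled, covariate-attached cell table for one survey year
#'
#' Simulation, effort accumulation, sighting assignment with exclusions,
#' labelling and covariate attachment for a single year.
#'
#' @param config a [scenario_config()].
#' @param truth a [synthetic_truth()].
#' @param year year index.
#' @param env the year's \code{env_stack} (generated if missing).
#' @param filters filter thresholds (see [run_config()]).
#' @param coastline optional coastline polyline.
#' @param fish_species if non-NULL, synthetic fish layers with these names
#'   are generated and attached.
#' @return list with \code{cells}, \code{track}, \code{sightings},
#'   \code{assignment}, \code{env}.
#' @export
survey_year_cells <- function(config, truth, year, env = NULL,
                              filters = run_config()$filters,
                              coastline = NULL, fish_species = NULL) {
  if (is.null(env)) env <- generate_env_stack(config, year)
  if (!is.null(fish_species)) {
    env <- generate_fish_fields(config, env, year, species = fish_species)
  }
  # the truth surface tracks the year's dynamic fields
  truth_y <- truth_for_year(truth, env)
  sv <- simulate_survey(config, env, truth_y, year)
  geom <- env$geom
  eff <- accumulate_effort(sv$track, geom,
                           min_speed_kn = filters$min_speed_kn)
  asg <- assign_sightings(sv$sightings, sv$track, geom,
                          max_speed_kn = filters$max_speed_kn,
                          max_visit_min = filters$max_visit_min)
  cells <- label_cells(eff, asg$counts, geom,
                       min_absence_s = filters$min_absence_s)
  frac_removed <- attr(cells, "fraction_zero_removed")
  cells <- attach_covariates(cells, env, geom, track = sv$track,
                             coastline = coastline)
  cells$year <- config$base_year + year - 1
  attr(cells, "fraction_zero_removed") <- frac_removed
  list(cells = cells, track = sv$track, sightings = sv$sightings,
       assignment = asg, env = env)
}

#' Daily effort and strip counts from a simulated survey
#'
#' Transect distance per calendar day (gaps over two minutes excluded) and
#' birds sighted within the counting strip per day.
#'
#' @param track track data.frame.
#' @param sightings sightings data.frame with \code{perp_distance_m}.
#' @param max_distance_m counting-strip half... full perpendicular limit
#'   (300 m).
#' @return data.frame \code{date}, \code{distance_km},
#'   \code{birds_within_300m}.
#' @export
survey_daily_summary <- function(track, sightings, max_distance_m = 300) {
  t <- parse_timestamp(track$timestamp)
  day <- as.Date(t)
  dt <- diff(as.numeric(t))
  # per-minute cadence: distance covered between consecutive on-effort records
  seg_km <- geosphere::distHaversine(
    cbind(track$lon[-nrow(track)], track$lat[-nrow(track)]),
    cbind(track$lon[-1], track$lat[-1])) / 1000
  keep <- dt <= 120 & day[-1] == day[-length(day)]
  dist <- tapply(seg_km[keep], day[-1][keep], sum)
  sd_ <- if (nrow(sightings)) {
    s <- sightings[sightings$perp_distance_m <= max_distance_m, , drop = FALSE]
    tapply(s$count, as.Date(parse_timestamp(s$timestamp)), sum)
  } else numeric(0)
  dates <- sort(unique(day))
  dk <- as.numeric(dist[as.character(dates)])
  bd <- as.numeric(sd_[as.character(dates)])
  out <- data.frame(date = dates,
                    distance_km = ifelse(is.na(dk), 0, dk),
                    birds_within_300m = ifelse(is.na(bd), 0, bd))
  rownames(out) <- NULL
  out[out$distance_km > 0, , drop = FALSE]
}

#' Run the full synthetic-survey pipeline
#'
#' Simulates every survey year, derives covariates, builds the labelled
#' cell table, selects a binomial GAM by constrained AIC, fits the balanced
#' random-forest ensemble with leave-one-year-out validation, estimates
#' strip-transect abundance per year, and (optionally) writes tables, maps,
#' metrics and a manifest to a run directory. Identical configuration and
#' seed give identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; \code{NULL} = no files
#'   written).
#' @param quiet suppress progress messages.
#' @return list with \code{cells}, \code{selection}, \code{gam_maps},
#'   \code{loyo}, \code{ensemble}, \code{rf_map}, \code{abundance},
#'   \code{area}, \code{metrics}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  sc_args <- config$scenario
  sc <- do.call(scenario_config, sc_args)
  say("stage simulate: ", sc$n_years, " year(s)")
  env1 <- generate_env_stack(sc, 1)
  truth <- synthetic_truth(sc, env1)
  years <- seq_len(sc$n_years)
  runs <- lapply(years, function(y) {
    survey_year_cells(sc, truth, y, env = if (y == 1) env1 else NULL,
                      filters = config$filters)
  })
  cells <- do.call(rbind, lapply(runs, `[[`, "cells"))
  frac_removed <- vapply(runs, function(r)
    attr(r$cells, "fraction_zero_removed"), numeric(1))

  say("stage prediction area")
  bound_years <- if (sc$n_years > 1) {
    (sc$base_year - 1) + seq_len(sc$n_years - 1)
  } else sc$base_year
  area <- build_prediction_area(cells[cells$year %in% bound_years, ],
                                env1$geom)

  say("stage gam")
  ocean_vars <- c("sst", "chlorophyll", "salinity", "depth")
  pool <- if (identical(config$model$gam_pool, "full")) {
    standard_candidate_pool("ocean", always = character(0))
  } else {
    enumerate_candidates(
      free = ocean_vars,
      exclusive = list(c("max_current", "strat_index")),
      always = character(0))
  }
  sel <- select_sdm(cells, pool, k = config$model$k)
  gam_maps <- lapply(years, function(y) {
    predict_map(sel$best, runs[[y]]$env, area)
  })
  lab <- cells[cells$label %in% c("presence", "absence"), ]
  gam_auc_year <- vapply(split(lab, lab$year), function(d) {
    if (length(unique(d$label == "presence")) < 2) return(NA_real_)
    compute_auc(d$label == "presence", predict(sel$best, d))
  }, numeric(1))
  gam_auc_pooled <- compute_auc(lab$label == "presence", predict(sel$best, lab))

  say("stage rf")
  rf_covars <- c(ocean_vars, "max_current", "strat_index", "roughness",
                 "aspect", "anomaly", "lat", "lon")
  rf_covars <- intersect(rf_covars, names(cells))
  loyo <- if (sc$n_years >= 2) {
    leave_one_year_out(cells, rf_covars, n_trees = config$model$n_trees,
                       sample_frac = config$model$sample_frac,
                       mtry_multipliers = config$model$mtry_multipliers,
                       cv_folds = config$model$cv_folds, seed = sc$seed)
  } else NULL
  bal <- balance_classes(cells, seed = sc$seed)
  ens <- fit_rf_ensemble(bal, rf_covars, n_trees = config$model$n_trees,
                         sample_frac = config$model$sample_frac,
                         mtry_multipliers = config$model$mtry_multipliers,
                         cv_folds = config$model$cv_folds, seed = sc$seed)
  rf_map <- predict_rf_map(ens, env1, area)

  say("stage abundance")
  daily <- lapply(years, function(y)
    survey_daily_summary(runs[[y]]$track, runs[[y]]$sightings))
  proto <- survey_protocol(sc$base_year + years - 1)
  area_override <- config$constants$area_km2
  area_km2 <- if (!is.null(area_override) && !is.na(area_override)) {
    area_override
  } else area$area_km2
  abund <- do.call(rbind, lapply(seq_along(years), function(i) {
    d <- daily[[i]]
    w <- proto$strip_width_km[i]
    dens <- pooled_density(sum(d$birds_within_300m), sum(d$distance_km), w)
    dv <- weighted_density_variance(d, w)
    est <- estimate_abundance(dens, dv, area_km2, year = proto$year[i])
    data.frame(year = est$year, distance_km = sum(d$distance_km),
               birds_within_300m = sum(d$birds_within_300m),
               density = est$density, density_variance = est$density_variance,
               abundance = round(est$abundance),
               abundance_variance = est$abundance_variance)
  }))

  metrics <- list(
    n_cells_labelled = sum(cells$label != "undetermined"),
    n_presence = sum(cells$label == "presence"),
    prevalence = base::mean(cells$label[cells$label != "undetermined"] == "presence"),
    fraction_zero_removed = base::mean(frac_removed, na.rm = TRUE),
    area_km2 = area_km2,
    gam_best = paste(sort(sel$best$covariates), collapse = "+"),
    gam_auc_by_year = as.list(gam_auc_year),
    gam_auc_pooled = gam_auc_pooled,
    loyo_auc = if (!is.null(loyo)) as.list(stats::setNames(loyo$auc, loyo$year)),
    ensemble_weights = as.list(stats::setNames(ens$weights,
                                               paste0("mtry", ens$mtry))),
    population_share_max = population_share(max(abund$abundance),
                                            config$constants$global_population),
    population_share_min = population_share(min(abund$abundance),
                                            config$constants$global_population)
  )

  result <- list(cells = cells, selection = sel, gam_maps = gam_maps,
                 loyo = loyo, ensemble = ens, rf_map = rf_map,
                 abundance = abund, area = area, metrics = metrics,
                 truth = truth, config = config)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  cells_out <- result$cells
  utils::write.csv(cells_out, p("cells.csv"), row.names = FALSE)
  utils::write.csv(result$selection$table, p("gam_selection.csv"),
                   row.names = FALSE)
  if (!is.null(result$loyo)) {
    utils::write.csv(result$loyo, p("loyo_auc.csv"), row.names = FALSE)
  }
  utils::write.csv(result$abundance, p("abundance.csv"), row.names = FALSE)
  for (y in seq_along(result$gam_maps)) {
    write_ascii_grid(result$gam_maps[[y]]$prob,
                     p(sprintf("gam_prob_year%d.asc", y)))
  }
  write_ascii_grid(result$rf_map, p("rf_prob.asc"))
  poly_ll <- unproject_xy(result$area$geom$proj,
                          result$area$polygon[, 1], result$area$polygon[, 2])
  geojson <- list(type = "Feature",
                  properties = list(area_km2 = result$area$area_km2),
                  geometry = list(type = "Polygon",
                                  coordinates = list(Map(c, poly_ll$lon,
                                                         poly_ll$lat))))
  jsonlite::write_json(geojson, p("prediction_area.geojson"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$metrics, p("metrics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_yaml <- yaml::as.yaml(unclass(result$config))
  manifest <- list(config_hash = fnv1a(cfg_yaml),
                   seed = result$config$scenario$seed,
                   package_version = as.character(utils::packageVersion("shearwaterSDM")),
                   config = unclass(result$config))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}
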