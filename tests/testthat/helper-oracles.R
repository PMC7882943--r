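# Independent brute-force oracles and shared fixtures.
# Every oracle here is written against the mathematical definition, not
# against the package implementation it checks.

# mean absolute difference to the 8 neighbours, by explicit loop
oracle_tri <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA_real_, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    diffs <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx) {
        diffs <- c(diffs, abs(m[i, j] - m[ii, jj]))
      }
    }
    out[i, j] <- mean(diffs)
  }
  out
}

# AUC by exhaustive pair comparison, ties counted one half
oracle_auc <- function(pos_scores, neg_scores) {
  s <- 0
  for (p in pos_scores) for (q in neg_scores) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos_scores) * length(neg_scores))
}

# distance-weighted variance by literal two-pass computation
oracle_weighted_var <- function(densities, weights) {
  m <- sum(weights * densities) / sum(weights)
  sum(weights * (densities - m)^2) / sum(weights)
}

# O(n^2) convex hull membership: a point is a hull vertex iff it is not
# strictly inside the hull = not expressible as a convex combination;
# simpler check: vertex iff some half-plane through it has all points on
# one side. Returns the hull point set (unordered).
oracle_hull_vertices <- function(x, y) {
  n <- length(x)
  keep <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      # direction from i to j defines a candidate supporting line
      nx_ <- -(y[j] - y[i]); ny_ <- x[j] - x[i]
      side <- nx_ * (x - x[i]) + ny_ * (y - y[i])
      if (all(side <= 1e-9) || all(side >= -1e-9)) keep[i] <- TRUE
    }
  }
  which(keep)
}

# simplex-constrained least squares by dense grid search
oracle_simplex_weights <- function(P, y, step = 0.01) {
  m <- ncol(P)
  stopifnot(m == 3)
  best <- NULL; best_sse <- Inf
  for (w1 in seq(0, 1, step)) for (w2 in seq(0, 1 - w1, step)) {
    w <- c(w1, w2, 1 - w1 - w2)
    sse <- sum((P %*% w - y)^2)
    if (sse < best_sse) { best_sse <- sse; best <- w }
  }
  list(weights = best, sse = best_sse)
}

# empirical semivariogram of a raster at given lag distances (km), fitted
# with a Gaussian model to estimate the correlation-length parameter
oracle_variogram_range <- function(r, max_lag_km = 60, n_pairs = 40000, seed = 1) {
  set.seed(seed)
  cc <- cell_centres(r$geom)
  i <- sample(nrow(cc), n_pairs, replace = TRUE)
  j <- sample(nrow(cc), n_pairs, replace = TRUE)
  d <- sqrt((cc$x[i] - cc$x[j])^2 + (cc$y[i] - cc$y[j])^2) / 1000
  g <- 0.5 * (r$values[i] - r$values[j])^2
  keep <- d > 0 & d <= max_lag_km
  bins <- cut(d[keep], breaks = seq(0, max_lag_km, length.out = 25))
  emp <- tapply(g[keep], bins, mean)
  mid <- (head(seq(0, max_lag_km, length.out = 25), -1) +
          tail(seq(0, max_lag_km, length.out = 25), -1)) / 2
  ok <- !is.na(emp)
  fit <- stats::nls(emp ~ sill * (1 - exp(-mid^2 / (2 * L^2))),
                    data = list(emp = as.numeric(emp[ok]), mid = mid[ok]),
                    start = list(sill = max(emp, na.rm = TRUE), L = 20))
  stats::coef(fit)[["L"]]
}

# ---- shared small synthetic fixtures ------------------------------------

small_extent <- c(lon_min = -6.0, lon_max = -4.6,
                  lat_min = 49.6, lat_max = 50.5)

# small grid with exact cell counts (uses the projection's own deg->m scale)
geom_of <- function(nx, ny, cell = 1000, lat0 = 50, lon0 = -5) {
  d2m <- 6371008.8 * pi / 180
  half_lat <- ny * cell / d2m / 2
  lat_c <- lat0 + half_lat  # centre so cos(lat0) in the projection is exact
  ext <- c(lon_min = lon0,
           lon_max = lon0 + nx * cell / (d2m * cos(lat_c * pi / 180)),
           lat_min = lat0, lat_max = lat0 + 2 * half_lat)
  g <- grid_geometry(ext, cell)
  stopifnot(g$nx == nx, g$ny == ny)
  g
}

# scenario with a known additive truth in {strat_index, sst}
recovery_scenario <- function(seed, n_years = 3, spacing = 8) {
  scenario_config(
    seed = seed, extent = small_extent, n_years = n_years,
    transect_spacing_km = spacing,
    suitability_coefficients = c(strat_index = 1.6, sst = -1.2),
    prevalence_target = 0.03, field_smoothness = 15
  )
}

# strongly separable truth for temporal-transferability experiments:
# coefficients large enough that the generating surface itself separates
# presences from absences well (the validation design, not a data model)
strong_scenario <- function(seed, n_years = 3, spacing = 8) {
  scenario_config(
    seed = seed, extent = small_extent, n_years = n_years,
    transect_spacing_km = spacing,
    suitability_coefficients = c(strat_index = 2.5, sst = -2.0),
    prevalence_target = 0.03, field_smoothness = 15
  )
}

# labelled multi-year cell table for a scenario (no anomaly smooth: the
# recovery experiments only use analytic layers, which keeps them fast)
recovery_cells <- function(sc, fish_species = NULL,
                           derive_layers = "strat_index",
                           fish_smoothness_km = NULL) {
  env1 <- generate_env_stack(sc, 1, derive_layers = derive_layers)
  truth <- synthetic_truth(sc, env1)
  runs <- lapply(seq_len(sc$n_years), function(y) {
    env <- if (y == 1) env1 else
      generate_env_stack(sc, y, derive_layers = derive_layers)
    if (!is.null(fish_species)) {
      env <- generate_fish_fields(sc, env, y, species = fish_species,
                                  smoothness_km = fish_smoothness_km)
    }
    survey_year_cells(sc, truth, y, env = env)
  })
  cells <- do.call(rbind, lapply(runs, `[[`, "cells"))
  attr(cells, "truth") <- truth
  attr(cells, "runs") <- runs
  cells
}

# cache shared across test files within one run
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}
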