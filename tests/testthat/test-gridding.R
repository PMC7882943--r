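track_geom <- function(nx = 5, ny = 5, cell = 1000) geom_of(nx, ny, cell)

# build a track data.frame from coordinates relative to the grid origin
make_track <- function(geom, x, y, t_s, speed_kn = 10, sea_state = 2) {
  ll <- unproject_xy(geom$proj, geom$xmin + x, geom$ymin + y)
  data.frame(timestamp = as.POSIXct("2015-10-05 08:00:00", tz = "UTC") + t_s,
             lon = ll$lon, lat = ll$lat, speed_kn = speed_kn,
             sea_state = sea_state)
}

cell_of <- function(geom, x, y) cell_at_xy(geom, geom$xmin + x, geom$ymin + y)

test_that("effort accumulation: containment, kinematics, conservation", {
  g <- track_geom()
  # 300 s wholly inside one cell
  tr <- make_track(g, c(1200, 1400), c(1500, 1500), c(0, 300))
  eff <- accumulate_effort(tr, g)
  expect_equal(eff[cell_of(g, 1300, 1500)], 300, tolerance = 1e-9)
  expect_equal(sum(eff), 300, tolerance = 1e-9)

  # straight crossing of a 1-km cell at 10 kn: 1000 m / 5.144 m/s = 194.4 s
  v <- 10 * 1852 / 3600
  tr2 <- make_track(g, c(500, 2500), c(1500, 1500), c(0, 2000 / v))
  eff2 <- accumulate_effort(tr2, g, max_gap_s = Inf)
  mid <- cell_of(g, 1500, 1500)
  expect_equal(eff2[mid], 1000 / v, tolerance = 1e-6)
  expect_equal(eff2[mid], 194.4, tolerance = 0.05)
  # a cell never entered accumulates nothing
  expect_equal(eff2[cell_of(g, 1500, 4500)], 0)
  # conservation: total effort = track duration (nothing stationary/out-of-grid)
  expect_equal(sum(eff2), 2000 / v, tolerance = 1e-9)

  # stationary records are excluded and reported
  tr3 <- make_track(g, c(1200, 1250, 1300), c(1500, 1500, 1500),
                    c(0, 60, 120), speed_kn = c(10, 0.2, 10))
  eff3 <- accumulate_effort(tr3, g)
  expect_equal(sum(eff3) + attr(eff3, "excluded_s"), 120, tolerance = 1e-9)
  expect_equal(attr(eff3, "excluded_s"), 120)  # both segments touch the slow fix

  expect_error(accumulate_effort(make_track(g, c(100, 200), c(100, 200),
                                            c(60, 0)), g), "increasing")
})

test_that("sighting assignment applies the speed and visit-duration exclusions", {
  g <- track_geom()
  # 20-minute visit to one cell: slow crawl with minute records
  xs <- seq(1050, 1950, length.out = 20)
  tr <- make_track(g, xs, rep(1500, 20), seq(0, by = 60, length.out = 20),
                   speed_kn = 1)
  s_in_long <- data.frame(timestamp = tr$timestamp[10], lon = tr$lon[10],
                          lat = tr$lat[10], count = 1)
  asg <- assign_sightings(s_in_long, tr, g)
  expect_equal(nrow(asg$included), 0)
  expect_equal(asg$exclusions$reason, "visit_duration")  # 20 min > 15 min

  # fast vessel: excluded by the 17-kn rule
  tr_fast <- make_track(g, c(500, 2500), c(1500, 1500), c(0, 300),
                        speed_kn = 18)
  s_fast <- data.frame(timestamp = tr_fast$timestamp[1], lon = tr_fast$lon[1],
                       lat = tr_fast$lat[1], count = 2)
  asg_f <- assign_sightings(s_fast, tr_fast, g)
  expect_equal(asg_f$exclusions$reason, "vessel_speed")

  # ordinary sighting at 10 kn, 4-minute visit: assigned to the bird's cell
  tr_ok <- make_track(g, seq(1100, 1900, length.out = 5), rep(1500, 5),
                      seq(0, 240, by = 60))
  s_ok <- data.frame(timestamp = tr_ok$timestamp[3],
                     lon = tr_ok$lon[3], lat = tr_ok$lat[3], count = 3)
  asg_ok <- assign_sightings(s_ok, tr_ok, g)
  expect_equal(nrow(asg_ok$exclusions), 0)
  expect_equal(asg_ok$counts[cell_of(g, 1500, 1500)], 3)

  # outside the grid: excluded with its reason; bookkeeping balances
  s_out <- data.frame(timestamp = tr_ok$timestamp[1], lon = 10, lat = 10, count = 1)
  both <- rbind(s_ok, s_out)
  asg_b <- assign_sightings(both, tr_ok, g)
  expect_equal(nrow(asg_b$included) + nrow(asg_b$exclusions), nrow(both))
  expect_true("outside_grid" %in% asg_b$exclusions$reason)
})

test_that("labelling applies the three-minute false-absence rule", {
  g <- track_geom(3, 1)
  eff <- c(180, 120, 60)
  cnt <- c(0, 0, 2)
  cells <- label_cells(eff, cnt, g)
  expect_equal(as.character(cells$label), c("absence", "undetermined", "presence"))
  # the label partition is exhaustive and exclusive
  expect_false(anyNA(cells$label))
  # fraction of zero-sighting cells removed as undetermined
  expect_equal(attr(cells, "fraction_zero_removed"), 0.5)
  expect_error(label_cells(c(-1, 0, 0), cnt, g), "negative")
})

test_that("covariate attachment: node values, coastline distance, sea state", {
  g <- track_geom()
  cc <- cell_centres(g)
  env <- env_stack(g, list(depth = -50 - (cc$y - g$ymin) / 100,
                           sst = 10 + (cc$x - g$xmin) / 1000))
  cells <- label_cells(rep(200, g$nx * g$ny), rep(0, g$nx * g$ny), g)
  # constant sea state along a track: the cell inherits it
  tr <- make_track(g, seq(500, 4500, by = 250), rep(500, 17),
                   seq(0, by = 60, length.out = 17), sea_state = 4)
  coast <- cbind(lon = c(g$extent["lon_min"], g$extent["lon_max"]),
                 lat = rep(g$extent["lat_max"], 2))
  out <- attach_covariates(cells, env, g, track = tr, coastline = coast)
  # cell centre sits on a raster node: bilinear returns the node value
  expect_equal(out$sst, 10 + (cc$x - g$xmin) / 1000)
  expect_equal(out$depth, -50 - (cc$y - g$ymin) / 100)
  expect_true(all(out$sea_state[!is.na(out$sea_state)] == 4))
  # coastline along the northern boundary: top-row centres are ~500 m away
  top <- out$cell_id > g$nx * (g$ny - 1)
  expect_equal(out$distance_to_coast[top], rep(0.5, sum(top)), tolerance = 0.01)
  # a coastline through a cell centre gives distance ~ 0
  coast2 <- cbind(lon = c(cc$lon[1] - 0.01, cc$lon[1] + 0.01),
                  lat = rep(cc$lat[1], 2))
  out2 <- attach_covariates(cells[1, ], env, g, coastline = coast2)
  expect_lt(out2$distance_to_coast, 0.05)
  # asking for sea state without a track leaves it absent, not wrong
  expect_false("sea_state" %in% names(attach_covariates(cells[1, ], env, g)))
})

test_that("prediction area: hull, clipping, area, and the hull oracle", {
  g <- track_geom(10, 10)
  # cell centres at the corners of a 2 km x 2 km square: hull area 4 km2
  ids <- cell_of(g, c(500, 2500, 500, 2500), c(500, 500, 2500, 2500))
  area <- build_prediction_area(data.frame(cell_id = ids), g)
  expect_equal(area$area_km2, 4, tolerance = 1e-9)

  # collinear centres: error
  col_ids <- cell_of(g, c(500, 1500, 2500), rep(500, 3))
  expect_error(build_prediction_area(data.frame(cell_id = col_ids), g),
               "collinear|degenerate")

  # hull of 100 random cells matches the O(n^2) supporting-line oracle
  set.seed(33)
  ids <- sample(g$nx * g$ny, 100)
  area2 <- build_prediction_area(data.frame(cell_id = ids), g)
  cc <- cell_centres(g)[unique(ids), ]
  ov <- oracle_hull_vertices(cc$x, cc$y)
  ox <- cc$x[ov]; oy <- cc$y[ov]
  ord <- order(atan2(oy - mean(oy), ox - mean(ox)))
  oracle_area <- abs(shearwaterSDM:::polygon_area(cbind(ox[ord], oy[ord]))) / 1e6
  expect_equal(area2$area_km2, oracle_area, tolerance = 1e-9)
  # every polygon corner is an oracle extreme point; on a lattice the oracle
  # also flags points lying on hull edges, which must sit on the boundary
  expect_true(all(paste(round(area2$polygon[, 1]), round(area2$polygon[, 2]))
                  %in% paste(round(ox), round(oy))))
  expect_true(all(shearwaterSDM:::on_polygon_edge(area2$polygon, ox, oy,
                                                  tol = 0.5)))

  # membership: all source points inside, far corner outside
  expect_true(all(point_in_area(area2, cc$x, cc$y)))
  expect_false(point_in_area(area, g$xmin + 9500, g$ymin + 9500))
})

test_that("effort + sightings bookkeeping is conserved on a simulated survey", {
  sc <- recovery_scenario(41, n_years = 1)
  env <- generate_env_stack(sc, 1, derive_layers = "strat_index")
  truth <- synthetic_truth(sc, env)
  sv <- simulate_survey(sc, env, truth, 1)
  eff <- accumulate_effort(sv$track, env$geom)
  t <- as.numeric(shearwaterSDM:::parse_timestamp(sv$track$timestamp))
  dt <- diff(t)
  on_effort <- sum(dt[dt <= 300])
  expect_equal(sum(eff) + attr(eff, "excluded_s"), on_effort, tolerance = 1)
  asg <- assign_sightings(sv$sightings, sv$track, env$geom)
  expect_equal(nrow(asg$included) + nrow(asg$exclusions), nrow(sv$sightings))
  expect_equal(sum(asg$counts), sum(sv$sightings$count[asg$included$row]))
})
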