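# brute-force subset-filter oracle for the constrained enumeration
oracle_enumerate <- function(all_vars, exclusive, lat_lon_pair = TRUE) {
  n <- length(all_vars)
  count <- 0
  for (code in 0:(2^n - 1)) {
    s <- all_vars[bitwAnd(code, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (g in exclusive) if (length(intersect(s, g)) > 1) ok <- FALSE
    if (lat_lon_pair) {
      # lat and lon only ever together, and never with distance to coast
      if (xor("lat" %in% s, "lon" %in% s)) ok <- FALSE
      if ("distance_to_coast" %in% s && "lat" %in% s) ok <- FALSE
    }
    if (ok) count <- count + 1
  }
  count
}

test_that("candidate enumeration honours the constraint groups", {
  # two unconstrained variables: all 2^2 subsets
  expect_length(enumerate_candidates(free = c("a", "b")), 4)
  # two mutually exclusive variables: none, A, B
  expect_length(enumerate_candidates(exclusive = list(c("a", "b"))), 3)
  # the full oceanographic pool vs the brute-force subset-filter oracle
  pool <- standard_candidate_pool("ocean", always = character(0))
  all_vars <- c("sst", "chlorophyll", "salinity", "depth", "max_current",
                "strat_index", "roughness", "anomaly", "aspect",
                "distance_to_coast", "lat", "lon")
  n_oracle <- oracle_enumerate(
    all_vars,
    exclusive = list(c("max_current", "strat_index"),
                     c("roughness", "anomaly", "aspect"),
                     c("distance_to_coast", "lat"),
                     c("distance_to_coast", "lon")))
  expect_equal(length(pool), n_oracle)
  expect_equal(length(pool), 576)
  # candidates are unique and each satisfies every constraint
  keys <- vapply(pool, function(s) paste(sort(s), collapse = "+"), character(1))
  expect_equal(anyDuplicated(keys), 0)
  for (s in pool) {
    expect_lte(length(intersect(s, c("max_current", "strat_index"))), 1)
    expect_lte(length(intersect(s, c("roughness", "anomaly", "aspect"))), 1)
    expect_false("distance_to_coast" %in% s && "lat" %in% s)
    expect_equal("lat" %in% s, "lon" %in% s)
  }
  # the always-include set is appended to every candidate
  with_ss <- standard_candidate_pool("fish", always = "sea_state")
  expect_true(all(vapply(with_ss, function(s) "sea_state" %in% s, logical(1))))
  expect_length(with_ss, 2^7)

  expect_error(enumerate_candidates(
    exclusive = list(c("a", "b"), c("b", "c"))), "two exclusive groups")
})

make_cells <- function(n, p = NULL, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n); noise <- rnorm(n)
  if (is.null(p)) p <- plogis(1.5 * x1 - x2)
  pres <- rbinom(n, 1, p)
  data.frame(label = factor(ifelse(pres == 1, "presence", "absence"),
                            levels = c("absence", "presence", "undetermined")),
             x1 = x1, x2 = x2, noise = noise)
}

test_that("intercept-only binomial fit reproduces the closed-form AIC", {
  cells <- data.frame(label = factor(rep(c("presence", "absence"), each = 5),
                                     levels = c("absence", "presence")))
  fit <- fit_sdm_gam(cells, character(0))
  expect_equal(as.numeric(predict(fit, cells)), rep(0.5, 10), tolerance = 1e-9)
  # -2 * 10 * log(0.5) + 2 = 15.863
  expect_equal(fit$aic, -2 * 10 * log(0.5) + 2, tolerance = 1e-6)
  expect_equal(round(fit$aic, 3), 15.863)
  expect_error(fit_sdm_gam(cells[cells$label == "presence", , drop = FALSE],
                           character(0)),
               "presences and absences")
})

test_that("noise covariates rarely improve AIC by more than the parameter cost", {
  hits <- 0
  for (r in 1:100) {
    cells <- make_cells(100, p = 0.4, seed = 1000 + r)
    f0 <- fit_sdm_gam(cells, character(0))
    f1 <- fit_sdm_gam(cells, "noise")
    if (f1$aic >= f0$aic - 2) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("a perfectly separating covariate gives in-sample AUC 1", {
  cells <- make_cells(60, seed = 3)
  cells$sep <- ifelse(cells$label == "presence", 1, 0) + seq_len(60) * 1e-4
  # complete separation makes mgcv warn about the step failure; the ordering
  # of the fitted probabilities is what matters here
  fit <- suppressWarnings(fit_sdm_gam(cells, "sep"))
  auc <- compute_auc(cells$label == "presence", predict(fit, cells))
  expect_equal(auc, 1)
})

test_that("AIC selection ranks correctly with deterministic tie-breaks", {
  cells <- make_cells(400, seed = 7)
  # single spec: delta AIC 0
  one <- select_sdm(cells, list("x1"))
  expect_equal(one$table$delta_aic, 0)
  # duplicate specs tie exactly; order is deterministic under rerun
  two <- select_sdm(cells, list(c("x1", "x2"), c("x2", "x1")))
  expect_equal(two$table$aic[1], two$table$aic[2], tolerance = 1e-9)
  two_b <- select_sdm(cells, list(c("x1", "x2"), c("x2", "x1")))
  expect_identical(two$table$model, two_b$table$model)
  # the true covariates beat noise-only and intercept-only candidates
  sel <- select_sdm(cells, list(character(0), "noise", c("x1", "x2"),
                                c("x1", "x2", "noise")))
  expect_true(all(c("x1", "x2") %in%
                    strsplit(sel$table$covariates[1], "\\+")[[1]]))
  # best-model AIC is the minimum of all converged AICs
  expect_equal(sel$table$aic[1], min(sel$table$aic))
  expect_equal(sel$best$aic, sel$table$aic[1])
})

test_that("probability maps are confined to the prediction area with valid CIs", {
  sc <- recovery_scenario(19, n_years = 1)
  env <- generate_env_stack(sc, 1, derive_layers = "strat_index")
  truth <- synthetic_truth(sc, env)
  yr <- survey_year_cells(sc, truth, 1, env = env)
  cells <- yr$cells
  area <- build_prediction_area(cells, env$geom)
  fit <- fit_sdm_gam(cells, c("sst", "strat_index"))
  maps <- predict_map(fit, env, area)
  cc <- cell_centres(env$geom)
  inside <- point_in_area(area, cc$x, cc$y)
  expect_true(all(is.na(maps$prob$values[!inside])))
  pv <- maps$prob$values[inside]
  expect_true(all(pv > 0 & pv < 1, na.rm = TRUE))
  expect_true(all(maps$ci_width$values[inside] >= 0, na.rm = TRUE))
  # intercept-only model: flat map at the training prevalence
  fit0 <- fit_sdm_gam(cells, character(0))
  m0 <- predict_map(fit0, env, area)
  lab <- cells[cells$label != "undetermined", ]
  expect_equal(unique(round(m0$prob$values[inside], 10)),
               round(mean(lab$label == "presence"), 10))
  # a model needing a covariate the stack lacks refuses to predict
  fit_bad <- fit_sdm_gam(transform(cells, ghost = rnorm(nrow(cells))), "ghost")
  expect_error(predict_map(fit_bad, env, area), "ghost")
})

test_that("confidence-interval widths shrink with training size", {
  gen <- function(n, seed) make_cells(n, seed = seed)
  small <- fit_sdm_gam(gen(200, 11), c("x1", "x2"))
  big <- fit_sdm_gam(gen(5000, 12), c("x1", "x2"))
  nd <- data.frame(x1 = c(-1, 0, 1), x2 = c(0.5, 0, -0.5))
  ci_w <- function(fit) {
    pr <- predict(fit$fit, nd, type = "link", se.fit = TRUE)
    plogis(pr$fit + 1.96 * pr$se.fit) - plogis(pr$fit - 1.96 * pr$se.fit)
  }
  expect_true(all(ci_w(big) < ci_w(small)))
})

test_that("AUC follows the Mann-Whitney definition with half ties", {
  expect_equal(compute_auc(c(TRUE, TRUE, FALSE, FALSE),
                           c(0.9, 0.8, 0.1, 0.2)), 1.0)
  expect_equal(compute_auc(c(TRUE, TRUE, FALSE, FALSE), rep(0.5, 4)), 0.5)
  expect_equal(compute_auc(c(TRUE, TRUE, FALSE, FALSE),
                           c(0.9, 0.4, 0.5, 0.1)), 0.75)
  # random instances vs the exhaustive pairwise oracle and pROC
  set.seed(12)
  for (r in 1:5) {
    lab <- c(rep(TRUE, 7), rep(FALSE, 13))
    p <- round(runif(20), 1)  # coarse grid forces ties
    got <- compute_auc(lab, p)
    expect_equal(got, oracle_auc(p[lab], p[!lab]), tolerance = 1e-12)
    expect_equal(got,
                 as.numeric(pROC::auc(pROC::roc(lab, p, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
  expect_error(compute_auc(rep(TRUE, 3), c(0.1, 0.2, 0.3)), "both classes")
})
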