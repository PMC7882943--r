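rf_cells <- function(n = 300, p_noise = 4, seed = 5) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * (p_noise + 1)), n))
  names(d) <- c("signal", paste0("n", seq_len(p_noise)))
  d$label <- factor(ifelse(d$signal > median(d$signal), "presence", "absence"),
                    levels = c("absence", "presence", "undetermined"))
  d
}

test_that("explanatory forest ranks a planted signal first and tracks OOB error", {
  d <- rf_cells(400)
  fit <- fit_explanatory_rf(d, c("signal", paste0("n", 1:4)),
                            n_trees = 300, seed = 2)
  expect_equal(fit$importance$variable[1], "signal")
  expect_equal(sort(fit$importance$rank), 1:5)
  expect_lt(fit$oob_error, 0.2)  # near-deterministic rule is easy
  expect_error(fit_explanatory_rf(d, c("signal", "ghost")), "ghost")
})

test_that("OOB bookkeeping uses only out-of-bag trees", {
  # recompute the forest's OOB vote fractions from per-tree predictions and
  # the inbag matrix; they must agree with the forest's own bookkeeping
  d <- rf_cells(80, seed = 9)
  covars <- c("signal", "n1", "n2")
  set.seed(1)
  fr <- randomForest::randomForest(
    x = d[, covars], y = droplevels(d$label), ntree = 50,
    replace = FALSE, sampsize = floor(0.66 * nrow(d)), keep.inbag = TRUE,
    keep.forest = TRUE)
  all_preds <- predict(fr, d[, covars], predict.all = TRUE)$individual
  oob_frac <- vapply(seq_len(nrow(d)), function(i) {
    oob <- fr$inbag[i, ] == 0
    mean(all_preds[i, oob] == "presence")
  }, numeric(1))
  expect_equal(unname(oob_frac), unname(fr$votes[, "presence"]),
               tolerance = 1e-9)
})

test_that("duplicated predictors share importance (collinearity spreading)", {
  d <- rf_cells(400, seed = 13)
  base <- fit_explanatory_rf(d, c("signal", "n1", "n2"), n_trees = 400, seed = 3)
  d2 <- d; d2$signal_copy <- d2$signal
  dup <- fit_explanatory_rf(d2, c("signal", "signal_copy", "n1", "n2"),
                            n_trees = 400, seed = 3)
  imp0 <- base$importance$importance[base$importance$variable == "signal"]
  pair <- sum(dup$importance$importance[
    dup$importance$variable %in% c("signal", "signal_copy")])
  expect_gt(pair / imp0, 0.5)
  expect_lt(pair / imp0, 2)
})

test_that("class balancing downsamples absences exactly and reproducibly", {
  # sparse survey: 179 presences among 8,107 labelled cells -> 358 rows
  d <- data.frame(label = factor(c(rep("presence", 179),
                                   rep("absence", 8107 - 179)),
                                 levels = c("absence", "presence", "undetermined")),
                  x = seq_len(8107))
  bal <- balance_classes(d, seed = 4)
  expect_equal(nrow(bal), 358)
  expect_equal(sum(bal$label == "presence"), sum(bal$label == "absence"))
  expect_identical(balance_classes(d, seed = 4)$x, bal$x)
  expect_false(identical(balance_classes(d, seed = 5)$x, bal$x))
  # already balanced: unchanged up to order
  d2 <- d[c(1:179, 180:358), ]
  expect_setequal(balance_classes(d2, seed = 1)$x, d2$x)
  d3 <- d[d$label == "absence", ]
  expect_error(balance_classes(d3), "no presence")
})

test_that("ensemble weights solve the simplex least-squares problem", {
  set.seed(21)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  # one member reproduces the labels, two are noise: its weight dominates
  P <- cbind(y * 0.98 + 0.01, runif(n), runif(n))
  w <- shearwaterSDM:::nnls_weights(P, y)
  expect_gte(w[1], 0.9)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # random problems: matches the dense simplex grid oracle and beats vertices
  for (r in 1:5) {
    set.seed(r)
    P <- matrix(runif(3 * 60), 60, 3)
    yy <- rbinom(60, 1, 0.5)
    w <- shearwaterSDM:::nnls_weights(P, yy)
    sse <- sum((P %*% w - yy)^2)
    grid <- oracle_simplex_weights(P, yy, step = 0.02)
    expect_lte(sse, grid$sse + 1e-9)
    vertex_sse <- apply(P, 2, function(col) sum((col - yy)^2))
    expect_lte(sse, min(vertex_sse) + 1e-9)
    # never better than the unconstrained non-negative solution (pracma)
    un <- pracma::lsqnonneg(P, yy)
    expect_gte(sse, sum((P %*% un$x - yy)^2) - 1e-9)
  }
})

test_that("fitted ensemble: weights on the simplex, CV optimality, degenerate cases", {
  d <- rf_cells(240, seed = 31)
  bal <- balance_classes(d, seed = 1)
  ens <- fit_rf_ensemble(bal, c("signal", "n1", "n2", "n3"), n_trees = 120,
                         cv_folds = 5, seed = 6)
  expect_true(all(ens$weights >= 0))
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_lte(ens$cv_error, min(ens$cv_member_error) + 1e-9)
  # reproducible under the same seed
  ens2 <- fit_rf_ensemble(bal, c("signal", "n1", "n2", "n3"), n_trees = 120,
                          cv_folds = 5, seed = 6)
  expect_identical(ens$weights, ens2$weights)
  # prediction is the weighted mean of member probabilities
  nd <- d[1:20, ]
  member_p <- vapply(ens$members, function(m)
    predict(m, nd, type = "prob")[, "presence"], numeric(20))
  expect_equal(predict(ens, nd), as.numeric(member_p %*% ens$weights),
               tolerance = 1e-12)
  # single distinct mtry: proceeds with a warning
  expect_warning(
    fit_rf_ensemble(bal, c("signal", "n1"), n_trees = 50, cv_folds = 3,
                    mtry_multipliers = c(1, 1), seed = 1),
    "fewer than 2")
})

test_that("leave-one-year-out validates across years", {
  # strong signal identical across years: high AUC everywhere; 2 years -> 2 rows
  d <- rf_cells(500, seed = 41)
  # make presences the minority class, as in a sparse survey
  d$label <- factor(ifelse(d$signal > quantile(d$signal, 0.65),
                           "presence", "absence"),
                    levels = c("absence", "presence", "undetermined"))
  d$year <- rep(2013:2014, length.out = nrow(d))
  tab <- leave_one_year_out(d, c("signal", "n1", "n2"), n_trees = 150,
                            cv_folds = 5, seed = 2)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$year, 2013:2014)
  expect_true(all(tab$auc > 0.8))
  # a held-out year with one class yields a missing AUC and a warning
  d1 <- rbind(d, transform(d[1:120, ], year = 2015, label = "absence"))
  expect_warning(tab1 <- leave_one_year_out(d1, c("signal", "n1"),
                                            n_trees = 60, cv_folds = 3),
                 "one class")
  expect_true(is.na(tab1$auc[tab1$year == 2015]))
})

test_that("ensemble probability map tracks the true suitability surface", {
  sc <- recovery_scenario(47, n_years = 2)
  cells <- cached("rfmap_cells", recovery_cells(sc))
  truth <- attr(cells, "truth")
  runs <- attr(cells, "runs")
  env <- runs[[1]]$env
  area <- build_prediction_area(cells, env$geom)
  bal <- balance_classes(cells, seed = 3)
  covars <- c("sst", "salinity", "chlorophyll", "depth", "max_current",
              "strat_index", "lat", "lon")
  ens <- fit_rf_ensemble(bal, covars, n_trees = 200, cv_folds = 5, seed = 3)
  map <- predict_rf_map(ens, env, area)
  ok <- !is.na(map$values)
  expect_true(all(map$values[ok] >= 0 & map$values[ok] <= 1))
  rho <- cor(map$values[ok], truth$suitability$values[ok], method = "spearman")
  expect_gt(rho, 0.5)
  # degenerate weights reproduce the single member's map
  ens1 <- ens; ens1$weights <- c(1, rep(0, length(ens$weights) - 1))
  map1 <- predict_rf_map(ens1, env, area)
  m1 <- predict(ens$members[[1]],
                env_cell_table(env, area$geom)[ok, ], type = "prob")[, "presence"]
  expect_equal(map1$values[ok], unname(m1), tolerance = 1e-12)
})
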