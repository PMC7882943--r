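# Random-forest presence/absence models: an explanatory forest with
# permutation importance, and a predictive class-balanced ensemble of
# forests differing in mtry, combined by non-negative least squares.

#' Fit the explanatory random forest
#'
#' 500 probability trees, each grown on a seeded random 66\% subsample of
#' the cells drawn without replacement, with \code{mtry} candidate
#' variables per split. Correlated predictors are kept (the forest spreads
#' importance across them) and fish abundances enter untransformed.
#' Permutation importance is the mean drop in out-of-bag accuracy when a
#' predictor is randomized.
#'
#' @param cells labelled cell table.
#' @param covariates predictor column names.
#' @param n_trees number of trees (default 500).
#' @param sample_frac per-tree subsample fraction (default 0.66, without
#'   replacement).
#' @param mtry predictors tried per split (default 4).
#' @param seed RNG seed for the forest.
#' @return object of class \code{sdm_rf}: \code{forest}, \code{importance}
#'   (data.frame variable/importance/rank), \code{oob_error} (out-of-bag
#'   misclassification rate), \code{covariates}.
#' @export
fit_explanatory_rf <- function(cells, covariates, n_trees = 500,
                               sample_frac = 0.66, mtry = 4, seed = 1) {
  d <- model_frame_sdm(cells)
  miss <- setdiff(covariates, names(d))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(d[, covariates, drop = FALSE])
  d <- d[cc, , drop = FALSE]
  if (length(unique(d$pres)) < 2) stop("need both classes")
  y <- factor(ifelse(d$pres == 1, "presence", "absence"),
              levels = c("absence", "presence"))
  forest <- with_stream(seed, 0, "explanatory_rf",
    randomForest::randomForest(
      x = d[, covariates, drop = FALSE], y = y,
      ntree = n_trees, mtry = min(mtry, length(covariates)),
      replace = FALSE, sampsize = max(2, floor(sample_frac * nrow(d))),
      importance = TRUE
    ))
  imp <- randomForest::importance(forest, type = 1, scale = FALSE)
  imp_df <- data.frame(variable = rownames(imp),
                       importance = as.numeric(imp[, 1]))
  imp_df <- imp_df[order(-imp_df$importance, imp_df$variable), ]
  imp_df$rank <- seq_len(nrow(imp_df))
  rownames(imp_df) <- NULL
  structure(list(forest = forest, importance = imp_df,
                 oob_error = as.numeric(forest$err.rate[n_trees, "OOB"]),
                 covariates = covariates),
            class = "sdm_rf")
}

#' @export
print.sdm_rf <- function(x, ...) {
  cat(sprintf("Explanatory random forest: %d trees, OOB error %.3f\n",
              x$forest$ntree, x$oob_error))
  cat("  top variables:",
      paste(utils::head(x$importance$variable, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.sdm_rf <- function(object, newdata, ...) {
  stats::predict(object$forest, newdata = newdata, type = "prob")[, "presence"]
}

#' Balance classes by downsampling absences
#'
#' Keeps every presence and a seeded uniform subsample of absences of equal
#' count, countering the strong class imbalance of sparse sightings.
#'
#' @param cells labelled cell table.
#' @param seed RNG seed for the absence subsample.
#' @return the balanced cell table (presences first, then sampled absences).
#' @export
balance_classes <- function(cells, seed = 1) {
  d <- cells[cells$label %in% c("presence", "absence"), , drop = FALSE]
  pres <- d[d$label == "presence", , drop = FALSE]
  abs_ <- d[d$label == "absence", , drop = FALSE]
  if (nrow(pres) == 0) stop("no presence cells: cannot balance")
  if (nrow(pres) > nrow(abs_)) stop("more presences than absences")
  if (nrow(pres) == nrow(abs_)) return(rbind(pres, abs_))
  idx <- with_stream(seed, 0, "balance",
                     sample(nrow(abs_), nrow(pres), replace = FALSE))
  rbind(pres, abs_[idx, , drop = FALSE])
}

#' Fit a class-balanced random-forest ensemble
#'
#' Member forests use mtry values \code{max(1, floor(m * sqrt(p)))} for
#' multipliers m (default 0.5, 1, 2 around the square-root default),
#' deduplicated. Member weights are the non-negative, sum-to-one least
#' squares of stratified cross-validated member predictions against the
#' 0/1 labels (exact simplex-constrained solution, so the ensemble's CV
#' squared error never exceeds any single member's); the ensemble
#' prediction is the weighted mean of member probabilities.
#'
#' @param cells balanced labelled cell table (see [balance_classes()]).
#' @param covariates predictor column names.
#' @param n_trees trees per member.
#' @param sample_frac per-tree subsample fraction (without replacement).
#' @param mtry_multipliers multipliers of \code{sqrt(p)}.
#' @param cv_folds stratified cross-validation folds for the weights.
#' @param seed RNG seed.
#' @return object of class \code{rf_ensemble}: \code{members},
#'   \code{mtry}, \code{weights}, \code{covariates}, \code{cv_error}.
#' @export
fit_rf_ensemble <- function(cells, covariates, n_trees = 500,
                            sample_frac = 0.66,
                            mtry_multipliers = c(0.5, 1, 2),
                            cv_folds = 10, seed = 1) {
  d <- model_frame_sdm(cells)
  cc <- stats::complete.cases(d[, covariates, drop = FALSE])
  d <- d[cc, , drop = FALSE]
  p <- length(covariates)
  mtries <- unique(pmin(p, pmax(1, floor(mtry_multipliers * sqrt(p)))))
  if (length(mtries) < 2) {
    warning("fewer than 2 distinct mtry values after deduplication; ",
            "proceeding with ", length(mtries))
  }
  y <- factor(ifelse(d$pres == 1, "presence", "absence"),
              levels = c("absence", "presence"))
  n <- nrow(d)
  grow <- function(rows, mtry, stream) {
    with_stream(seed, stream, paste0("member_mtry", mtry),
      randomForest::randomForest(
        x = d[rows, covariates, drop = FALSE], y = y[rows],
        ntree = n_trees, mtry = mtry, replace = FALSE,
        sampsize = max(2, floor(sample_frac * length(rows)))
      ))
  }
  # stratified CV folds for the meta-weights
  folds <- integer(n)
  for (cls in levels(y)) {
    rows <- which(y == cls)
    kf <- min(cv_folds, length(rows))
    folds[rows] <- with_stream(seed, 0, paste0("folds_", cls),
                               sample(rep_len(seq_len(kf), length(rows))))
  }
  P <- matrix(NA_real_, n, length(mtries))
  for (f in sort(unique(folds))) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[tr])) < 2) next
    for (j in seq_along(mtries)) {
      fit <- grow(tr, mtries[j], 1000 + f)
      P[te, j] <- stats::predict(fit, d[te, covariates, drop = FALSE],
                                 type = "prob")[, "presence"]
    }
  }
  ok <- stats::complete.cases(P)
  w <- nnls_weights(P[ok, , drop = FALSE], d$pres[ok])
  members <- lapply(seq_along(mtries), function(j) grow(seq_len(n), mtries[j], 0))
  cv_pred <- as.numeric(P[ok, , drop = FALSE] %*% w)
  structure(list(members = members, mtry = mtries, weights = w,
                 covariates = covariates,
                 cv_error = base::mean((cv_pred - d$pres[ok])^2),
                 cv_member_error = colMeans((P[ok, , drop = FALSE] -
                                               d$pres[ok])^2)),
            class = "rf_ensemble")
}

# Least-squares weights on the probability simplex: minimize ||Pw - y||^2
# subject to w >= 0, sum(w) = 1. Exact active-set enumeration (the member
# count is tiny): every support set is solved as an equality-constrained
# least-squares KKT system and the feasible solution with the smallest
# error wins. Single-member supports are always feasible, so the optimum
# is never worse than any individual member.
nnls_weights <- function(P, y) {
  m <- ncol(P)
  best <- NULL; best_sse <- Inf
  for (code in seq_len(2^m - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(m) - 1)) > 0)
    Ps <- P[, S, drop = FALSE]
    A <- rbind(cbind(crossprod(Ps), rep(1, length(S))),
               c(rep(1, length(S)), 0))
    b <- c(crossprod(Ps, y), 1)
    sol <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_along(S)]
    if (any(w < -1e-10)) next
    w <- pmax(w, 0); w <- w / sum(w)
    sse <- sum((Ps %*% w - y)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- numeric(m); best[S] <- w
    }
  }
  if (is.null(best)) best <- rep(1 / m, m)
  best
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat("Random-forest ensemble:\n")
  for (j in seq_along(x$members)) {
    cat(sprintf("  mtry %d: weight %.3f\n", x$mtry[j], x$weights[j]))
  }
  cat(sprintf("  CV squared error %.4f\n", x$cv_error))
  invisible(x)
}

#' Weighted ensemble probability of presence
#' @param object an \code{rf_ensemble}.
#' @param newdata data.frame with the ensemble covariates.
#' @param ... unused.
#' @export
predict.rf_ensemble <- function(object, newdata, ...) {
  probs <- vapply(object$members, function(m) {
    stats::predict(m, newdata, type = "prob")[, "presence"]
  }, numeric(nrow(newdata)))
  probs <- matrix(probs, nrow = nrow(newdata))
  as.numeric(probs %*% object$weights)
}

#' Leave-one-year-out validation of the ensemble
#'
#' For each survey year, balances and fits an ensemble on all other years,
#' predicts every labelled cell of the held-out year (unbalanced), and
#' reports the AUC. Years whose labelled cells are single-class get a
#' missing AUC with a warning.
#'
#' @param cells labelled cell table with a \code{year} column.
#' @param covariates predictor column names.
#' @param n_trees,sample_frac,mtry_multipliers,cv_folds,seed passed to
#'   [fit_rf_ensemble()].
#' @return data.frame with \code{year}, \code{n}, \code{n_presence},
#'   \code{auc}.
#' @export
leave_one_year_out <- function(cells, covariates, n_trees = 500,
                               sample_frac = 0.66,
                               mtry_multipliers = c(0.5, 1, 2),
                               cv_folds = 10, seed = 1) {
  years <- sort(unique(cells$year))
  if (length(years) < 2) stop("need at least 2 years for leave-one-year-out")
  out <- lapply(seq_along(years), function(i) {
    yr <- years[i]
    train <- cells[cells$year != yr, , drop = FALSE]
    test <- cells[cells$year == yr &
                    cells$label %in% c("presence", "absence"), , drop = FALSE]
    bal <- balance_classes(train, seed = seed + i)
    ens <- fit_rf_ensemble(bal, covariates, n_trees = n_trees,
                           sample_frac = sample_frac,
                           mtry_multipliers = mtry_multipliers,
                           cv_folds = cv_folds, seed = seed + i)
    ok <- stats::complete.cases(test[, covariates, drop = FALSE])
    test <- test[ok, , drop = FALSE]
    n_pres <- sum(test$label == "presence")
    auc <- if (nrow(test) == 0 || n_pres == 0 || n_pres == nrow(test)) {
      warning("held-out year ", yr, " has one class; AUC missing")
      NA_real_
    } else {
      compute_auc(test$label == "presence", predict(ens, test))
    }
    data.frame(year = yr, n = nrow(test),
               n_presence = sum(test$label == "presence"), auc = auc)
  })
  do.call(rbind, out)
}

#' Map the ensemble probability of presence
#'
#' Weighted member probability for every cell inside the prediction area,
#' missing outside and wherever a covariate is missing.
#'
#' @param ensemble an \code{rf_ensemble}.
#' @param env an \code{env_stack}.
#' @param area a \code{prediction_area}.
#' @param coastline optional coastline polyline if distance-to-coast is a
#'   covariate.
#' @return a probability \code{grid_raster}.
#' @export
predict_rf_map <- function(ensemble, env, area, coastline = NULL) {
  tbl <- env_cell_table(env, area$geom, coastline = coastline)
  miss <- setdiff(ensemble$covariates, names(tbl))
  if (length(miss)) stop("missing layers for prediction: ",
                         paste(miss, collapse = ", "))
  inside <- point_in_area(area, tbl$x, tbl$y)
  use <- inside & stats::complete.cases(tbl[, ensemble$covariates, drop = FALSE])
  prob <- rep(NA_real_, nrow(tbl))
  if (any(use)) prob[use] <- predict(ensemble, tbl[use, , drop = FALSE])
  grid_raster(area$geom, prob, "rf_prob_presence")
}
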