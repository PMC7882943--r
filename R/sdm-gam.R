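# Binomial additive species-distribution models with constrained AIC
# selection. Smooths are deliberately small (basis dimension 4) and
# penalized by REML, trading flexibility for extrapolation behaviour.

#' Enumerate candidate covariate sets under constraint groups
#'
#' Builds every covariate subset compatible with the stated collinearity
#' constraints: free variables may appear in any combination; from each
#' exclusive group at most one member may appear; each choice group
#' contributes exactly one of its alternatives (one alternative may be the
#' empty set, and an alternative may bundle several variables, e.g.
#' latitude + longitude). Every candidate is augmented with the
#' always-include set. Order is deterministic.
#'
#' @param free character vector of unconstrained variables.
#' @param exclusive list of character vectors; at most one member of each
#'   may enter a model.
#' @param choices list of choice groups, each a list of character vectors
#'   (use \code{character(0)} for "none").
#' @param always character vector included in every candidate (e.g. sea
#'   state in explanatory models).
#' @return list of character vectors (candidate covariate sets).
#' @export
enumerate_candidates <- function(free = character(), exclusive = list(),
                                 choices = list(), always = character()) {
  ex_all <- unlist(exclusive)
  if (anyDuplicated(ex_all)) {
    stop("variable in two exclusive groups: ",
         paste(unique(ex_all[duplicated(ex_all)]), collapse = ", "))
  }
  # each exclusive group becomes a choice group {none, each member}
  for (g in exclusive) {
    choices[[length(choices) + 1]] <- c(list(character(0)), as.list(g))
  }
  # free variables: {absent, present} each
  for (v in free) choices[[length(choices) + 1]] <- list(character(0), v)
  if (!length(choices)) return(list(unique(always)))
  idx <- do.call(expand.grid, lapply(choices, function(g) seq_along(g)))
  out <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    vars <- character(0)
    for (cg in seq_along(choices)) vars <- c(vars, choices[[cg]][[idx[r, cg]]])
    out[[r]] <- unique(c(vars, always))
  }
  out
}

#' Standard candidate pools for oceanographic and fish models
#'
#' The oceanographic pool: SST, chlorophyll, salinity and depth are free;
#' maximum current speed and stratification index are mutually exclusive;
#' roughness, anomaly and aspect are mutually exclusive; location enters as
#' none, distance-to-coast, or latitude + longitude (never both location
#' representations). The fish pool is the seven species, unconstrained.
#' Fish and oceanographic variables never co-occur: they form separate
#' model sets compared only at the end.
#'
#' @param type \code{"ocean"} or \code{"fish"}.
#' @param always character vector added to every model (sea state for the
#'   explanatory analysis; empty for predictive models).
#' @param location include the location choice group (drop for reduced
#'   pools).
#' @return list of candidate covariate sets.
#' @export
standard_candidate_pool <- function(type = c("ocean", "fish"),
                                    always = "sea_state", location = TRUE) {
  type <- match.arg(type)
  if (type == "ocean") {
    enumerate_candidates(
      free = c("sst", "chlorophyll", "salinity", "depth"),
      exclusive = list(c("max_current", "strat_index"),
                       c("roughness", "anomaly", "aspect")),
      choices = if (location) {
        list(list(character(0), "distance_to_coast", c("lat", "lon")))
      } else list(),
      always = always
    )
  } else {
    enumerate_candidates(
      free = c("mackerel", "sprat", "anchovy", "sardine", "horse_mackerel",
               "herring", "boarfish"),
      always = always
    )
  }
}

model_frame_sdm <- function(cells) {
  if (!"label" %in% names(cells)) stop("cells need a 'label' column")
  d <- cells[cells$label %in% c("presence", "absence"), , drop = FALSE]
  d$pres <- as.integer(d$label == "presence")
  d
}

#' Fit a binomial additive model for presence/absence
#'
#' Penalized logistic additive model: one thin-plate smooth with basis
#' dimension \code{k} per continuous covariate, smoothing parameters
#' estimated by REML. Covariates with too few distinct values enter
#' linearly. Non-convergent fits are flagged rather than raised, with AIC
#' recorded as missing.
#'
#' @param cells labelled cell table (rows with label presence/absence used).
#' @param covariates character vector of covariate columns (empty =
#'   intercept-only).
#' @param k basis dimension per smooth (default 4).
#' @return object of class \code{sdm_gam} with elements \code{fit} (the
#'   mgcv fit), \code{covariates}, \code{aic}, \code{converged}, \code{n}.
#' @export
fit_sdm_gam <- function(cells, covariates = character(), k = 4) {
  d <- model_frame_sdm(cells)
  if (length(unique(d$pres)) < 2) stop("need both presences and absences")
  miss <- setdiff(covariates, names(d))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  terms <- vapply(covariates, function(v) {
    if (is.numeric(d[[v]]) && length(unique(d[[v]])) > k) {
      sprintf("s(%s, k = %d)", v, k)
    } else v
  }, character(1))
  fml <- stats::as.formula(paste("pres ~", if (length(terms))
    paste(terms, collapse = " + ") else "1"))
  fit <- tryCatch(
    mgcv::gam(fml, family = stats::binomial(), data = d, method = "REML"),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && isTRUE(fit$converged) &&
    !any(!is.finite(stats::coef(fit)))
  structure(list(
    covariates = covariates, fit = fit,
    aic = if (converged) stats::AIC(fit) else NA_real_,
    converged = converged, n = nrow(d), k = k, formula = fml
  ), class = "sdm_gam")
}

#' @export
print.sdm_gam <- function(x, ...) {
  cat("Binomial additive SDM (k =", x$k, ", REML)\n")
  cat("  covariates:", if (length(x$covariates))
    paste(x$covariates, collapse = ", ") else "(intercept only)", "\n")
  cat(sprintf("  n = %d, AIC = %.3f, converged = %s\n",
              x$n, x$aic, x$converged))
  invisible(x)
}

#' @export
summary.sdm_gam <- function(object, ...) summary(object$fit, ...)

#' @export
coef.sdm_gam <- function(object, ...) stats::coef(object$fit)

#' Predicted probability of presence
#' @param object an \code{sdm_gam}.
#' @param newdata data.frame with the model's covariates.
#' @param type \code{"response"} (probability) or \code{"link"}.
#' @param se.fit also return standard errors (link scale).
#' @param ... unused.
#' @export
predict.sdm_gam <- function(object, newdata, type = "response",
                            se.fit = FALSE, ...) {
  stats::predict(object$fit, newdata = newdata, type = type, se.fit = se.fit)
}

#' Fit and rank candidate models by AIC
#'
#' Fits every candidate covariate set, drops non-convergent fits with a
#' warning, and ranks the remainder by AIC (ties broken by fewer covariates,
#' then lexicographic covariate names, for determinism).
#'
#' @param cells labelled cell table.
#' @param specs list of covariate sets (see [enumerate_candidates()]).
#' @param k basis dimension per smooth.
#' @param keep_fits keep every fitted model (memory-heavy); default keeps
#'   only the best.
#' @return object of class \code{sdm_selection}: \code{table} (ranked
#'   data.frame with model, covariates, aic, delta_aic), \code{best} (the
#'   refitted best \code{sdm_gam}).
#' @export
select_sdm <- function(cells, specs, k = 4, keep_fits = FALSE) {
  fits <- lapply(specs, function(sp) fit_sdm_gam(cells, sp, k = k))
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!any(conv)) stop("no candidate model converged")
  if (any(!conv)) warning(sum(!conv), " non-convergent fit(s) dropped from ranking")
  tab <- data.frame(
    model = seq_along(specs),
    covariates = vapply(specs, function(s)
      paste(sort(s), collapse = "+"), character(1)),
    n_covariates = lengths(specs),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    converged = conv
  )
  keep <- tab[tab$converged, , drop = FALSE]
  ord <- order(keep$aic, keep$n_covariates, keep$covariates)
  keep <- keep[ord, , drop = FALSE]
  keep$delta_aic <- keep$aic - keep$aic[1]
  rownames(keep) <- NULL
  structure(list(table = keep, best = fits[[keep$model[1]]],
                 fits = if (keep_fits) fits else NULL),
            class = "sdm_selection")
}

#' @export
print.sdm_selection <- function(x, n = 5, ...) {
  cat("AIC model selection:", nrow(x$table), "converged candidates\n")
  print(utils::head(x$table[, c("covariates", "aic", "delta_aic")], n),
        row.names = FALSE)
  invisible(x)
}

#' Covariate table at cell centres for prediction
#'
#' Dynamic layers are extracted bilinearly at cell centres, other layers as
#' cell values; centre lat/lon and optional distance-to-coast are appended.
#'
#' @param env an \code{env_stack}.
#' @param geom the analysis grid (defaults to the stack's grid).
#' @param coastline optional coastline polyline (lon/lat matrix).
#' @param dynamic_layers layers extracted bilinearly.
#' @return data.frame with \code{cell_id}, \code{x}, \code{y}, \code{lon},
#'   \code{lat} and one column per layer.
#' @export
env_cell_table <- function(env, geom = env$geom, coastline = NULL,
                           dynamic_layers = c("sst", "salinity", "chlorophyll")) {
  cc <- cell_centres(geom)
  out <- cc
  same <- same_geometry(env$geom, geom)
  for (nm in names(env$layers)) {
    r <- env$layers[[nm]]
    out[[nm]] <- if (nm %in% dynamic_layers) {
      suppressWarnings(extract_bilinear(r, x = cc$x, y = cc$y))
    } else if (same) r$values else cell_mean_extract(r, geom, cc$cell_id)
  }
  if (!is.null(coastline)) {
    out$distance_to_coast <- distance_to_polyline_km(cc$lon, cc$lat, coastline)
  }
  out
}

#' Predict probability-of-presence and CI-width maps
#'
#' Predicts inside the prediction area only (missing outside). The
#' confidence-interval width raster is the difference between the upper and
#' lower 95\% bound, each obtained by inverse-link transform of the linear
#' predictor +/- 1.96 standard errors.
#'
#' @param model an \code{sdm_gam}.
#' @param env an \code{env_stack} covering the area.
#' @param area a \code{prediction_area}.
#' @param coastline optional coastline polyline if the model uses
#'   distance-to-coast.
#' @return list with \code{prob} and \code{ci_width} rasters.
#' @export
predict_map <- function(model, env, area, coastline = NULL) {
  tbl <- env_cell_table(env, area$geom, coastline = coastline)
  miss <- setdiff(model$covariates, names(tbl))
  if (length(miss)) {
    stop("model covariates not available for prediction: ",
         paste(miss, collapse = ", "))
  }
  inside <- point_in_area(area, tbl$x, tbl$y)
  use <- inside & stats::complete.cases(tbl[, model$covariates, drop = FALSE])
  prob <- rep(NA_real_, nrow(tbl))
  ciw <- rep(NA_real_, nrow(tbl))
  if (any(use)) {
    pr <- stats::predict(model$fit, newdata = tbl[use, , drop = FALSE],
                         type = "link", se.fit = TRUE)
    prob[use] <- stats::plogis(pr$fit)
    ciw[use] <- stats::plogis(pr$fit + 1.96 * pr$se.fit) -
                stats::plogis(pr$fit - 1.96 * pr$se.fit)
  }
  list(prob = grid_raster(area$geom, prob, "prob_presence"),
       ci_width = grid_raster(area$geom, ciw, "ci_width"))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly chosen presence is scored above a randomly
#' chosen absence, ties counted one half.
#'
#' @param labels presence/absence labels: logical, 0/1, or a factor with a
#'   \code{"presence"} level.
#' @param probabilities numeric scores.
#' @return AUC in [0,1].
#' @export
compute_auc <- function(labels, probabilities) {
  pos <- if (is.factor(labels)) labels == "presence" else as.logical(labels)
  ok <- !is.na(pos) & !is.na(probabilities)
  pos <- pos[ok]; p <- probabilities[ok]
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(p)  # midranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
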