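# Strip-transect abundance: pooled density, day-weighted variance, and
# density-multiplication up to the prediction area.

#' Survey protocol: observer sides and strip width per year
#'
#' One observer side (300 m strip) in 2013-2014; two sides (600 m strip)
#' from 2015 on. Birds count toward density only within 300 m of the
#' transect, where detectability is taken as complete; the 1,000 m limit
#' applies to the distribution modelling, not to density.
#'
#' @param years integer vector of survey years.
#' @param two_side_from first year with observers on both sides (2015).
#' @return data.frame with \code{year}, \code{sides}, \code{strip_width_km}.
#' @export
survey_protocol <- function(years, two_side_from = 2015) {
  sides <- ifelse(years >= two_side_from, 2L, 1L)
  data.frame(year = years, sides = sides, strip_width_km = 0.3 * sides)
}

#' Pooled strip-transect density for one year
#'
#' Birds seen within the counting strip divided by the total area searched:
#' total transect distance times strip width.
#'
#' @param birds total birds within 300 m of the transect.
#' @param distance_km total transect distance (km).
#' @param strip_width_km strip width (km): 0.3 or 0.6 by protocol.
#' @return density in birds/km^2.
#' @export
pooled_density <- function(birds, distance_km, strip_width_km) {
  if (distance_km <= 0) stop("total transect distance must be positive")
  if (birds < 0) stop("negative bird count")
  birds / (distance_km * strip_width_km)
}

#' Day-weighted variance of strip-transect density
#'
#' Variance of per-day densities across survey days, weighted by the
#' transect distance covered each day: with weights \eqn{w_d} = daily
#' distance and weighted mean \eqn{\bar D}, the variance is
#' \eqn{\sum w_d (D_d - \bar D)^2 / \sum w_d}.
#'
#' @param daily data.frame with \code{distance_km} and
#'   \code{birds_within_300m} per day.
#' @param strip_width_km strip width (km).
#' @return weighted variance of density (birds^2/km^4); 0 with a warning
#'   for a single day.
#' @export
weighted_density_variance <- function(daily, strip_width_km) {
  if (any(daily$distance_km <= 0)) stop("daily distances must be positive")
  if (nrow(daily) < 2) {
    warning("only one survey day: density variance is 0")
    return(0)
  }
  D <- daily$birds_within_300m / (daily$distance_km * strip_width_km)
  w <- daily$distance_km
  Dbar <- sum(w * D) / sum(w)
  sum(w * (D - Dbar)^2) / sum(w)
}

#' Density-multiplication abundance estimate
#'
#' Abundance is density times the prediction-area size; the abundance
#' variance multiplies the density variance by the area (not its square),
#' matching how the published variances scale — see the package vignette
#' for the caveat and \code{propagate_squared} for the conventional
#' delta-method alternative.
#'
#' @param density birds/km^2.
#' @param density_variance day-weighted density variance.
#' @param area_km2 prediction-area size (km^2); 41,771 for the Channel /
#'   Celtic Sea prediction polygon.
#' @param year optional year label.
#' @param propagate_squared multiply the variance by \code{area_km2^2}
#'   instead (conventional propagation for a scaled random variable).
#' @return object of class \code{abundance_estimate}.
#' @export
estimate_abundance <- function(density, density_variance, area_km2 = 41771,
                               year = NA, propagate_squared = FALSE) {
  if (area_km2 <= 0) stop("area must be positive")
  if (density < 0) stop("negative density")
  if (density_variance < 0) stop("negative density variance")
  av <- density_variance * if (propagate_squared) area_km2^2 else area_km2
  structure(list(year = year, density = density,
                 density_variance = density_variance,
                 abundance = density * area_km2,
                 abundance_variance = av, area_km2 = area_km2),
            class = "abundance_estimate")
}

#' @export
print.abundance_estimate <- function(x, ...) {
  cat(sprintf(
    "abundance_estimate%s: density %s birds/km2 (var %s); abundance %d (var %s) over %s km2\n",
    if (is.na(x$year)) "" else paste0(" [", x$year, "]"),
    signif(x$density, 2), signif(x$density_variance, 2),
    round(x$abundance), signif(x$abundance_variance, 3),
    format(x$area_km2, big.mark = ",")))
  invisible(x)
}

#' Per-year abundance from an annual survey summary
#'
#' Runs the pooled-density / density-multiplication chain for each year of
#' a summary table (as published or as produced by a synthetic survey).
#'
#' @param summary data.frame with \code{year}, \code{distance_km},
#'   \code{birds_within_300m}.
#' @param area_km2 prediction-area size (km^2).
#' @param protocol optional protocol table (defaults to
#'   \code{survey_protocol(summary$year)}).
#' @return data.frame with year, strip width, density, abundance (rounded
#'   to whole birds) and the exact product in \code{abundance_raw}.
#' @export
abundance_by_year <- function(summary, area_km2 = 41771, protocol = NULL) {
  if (is.null(protocol)) protocol <- survey_protocol(summary$year)
  w <- protocol$strip_width_km[match(summary$year, protocol$year)]
  dens <- mapply(pooled_density, summary$birds_within_300m,
                 summary$distance_km, w)
  data.frame(year = summary$year, strip_width_km = w, density = dens,
             abundance = round(dens * area_km2),
             abundance_raw = dens * area_km2)
}

#' Share of the global population
#'
#' @param abundance estimated number of birds.
#' @param global_population global population size (30,600 for the Balearic
#'   shearwater).
#' @return percentage, rounded to a whole percent.
#' @export
population_share <- function(abundance, global_population = 30600) {
  if (global_population <= 0) stop("global population must be positive")
  round(100 * abundance / global_population)
}

#' Published annual survey summary (western Channel / Celtic Sea, 2013-2017)
#'
#' Per-year transect distance, birds within 300 m (with flying counts),
#' survey days, total birds and occupied 1-km cells, as published for the
#' 2013-2017 Balearic shearwater surveys. Shipped as a plain-text CSV; the
#' printed per-year rows are the inputs to the abundance chain.
#'
#' @return data.frame with columns \code{year}, \code{distance_km},
#'   \code{birds_within_300m}, \code{flying_within_300m}, \code{days},
#'   \code{birds_total}, \code{cells_with_birds}.
#' @export
survey_summary <- function() {
  path <- system.file("extdata", "survey_summary.csv", package = "shearwaterSDM")
  utils::read.csv(path)
}

#' Whole-survey bookkeeping totals from the per-year summary rows
#'
#' Sums the annual rows to whole-survey totals and reports the occupied-cell
#' fraction of the labelled (presence or filtered absence) cells.
#'
#' @param summary annual survey summary (see [survey_summary()]).
#' @param labelled_cells total number of labelled cells across the survey
#'   (8,107 for the 2013-2017 Channel / Celtic Sea surveys).
#' @return list with \code{distance_km}, \code{days}, \code{birds},
#'   \code{occupied_cells} and \code{occupied_pct} (one decimal place).
#' @export
survey_totals <- function(summary, labelled_cells = 8107) {
  list(distance_km = sum(summary$distance_km),
       days = sum(summary$days),
       birds = sum(summary$birds_total),
       occupied_cells = sum(summary$cells_with_birds),
       occupied_pct = round(100 * sum(summary$cells_with_birds) /
                              labelled_cells, 1))
}

#' Format the annual abundance table for reporting
#'
#' Densities are printed to two significant figures and abundances to whole
#' birds, with thousands separators on distances and abundances.
#'
#' @param summary annual summary (see [abundance_by_year()]); needs
#'   \code{flying_within_300m} for the bracketed flying counts when present.
#' @param area_km2 prediction-area size (km^2).
#' @param variances optional named numeric (by year) of density variances
#'   to print alongside.
#' @return data.frame of formatted character columns.
#' @export
make_abundance_table <- function(summary, area_km2 = 41771, variances = NULL) {
  ab <- abundance_by_year(summary, area_km2)
  fmt_int <- function(x) format(round(x), big.mark = ",", trim = TRUE)
  birds <- if ("flying_within_300m" %in% names(summary)) {
    sprintf("%d [%d]", summary$birds_within_300m, summary$flying_within_300m)
  } else as.character(summary$birds_within_300m)
  dens <- vapply(seq_len(nrow(ab)), function(i) {
    d <- format(signif(ab$density[i], 2), scientific = FALSE, trim = TRUE)
    if (!is.null(variances)) {
      v <- variances[as.character(ab$year[i])]
      av <- v * area_km2
      d <- sprintf("%s (%s)", d, format(signif(v, 2), scientific = FALSE, trim = TRUE))
      return(c(d, sprintf("%s (%s)", fmt_int(ab$abundance[i]),
                          fmt_int(signif(av, 3)))))
    }
    c(d, fmt_int(ab$abundance[i]))
  }, character(2))
  data.frame(year = ab$year,
             distance_km = fmt_int(summary$distance_km),
             birds = birds,
             density = dens[1, ],
             abundance = dens[2, ])
}
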