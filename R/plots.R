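# Minimal base-graphics methods: raster images and partial effects.

#' Plot a raster layer
#'
#' Simple \code{image()} display in the metric grid coordinates, low values
#' dark, with an optional polygon overlay (e.g. a prediction area).
#'
#' @param x a \code{grid_raster}.
#' @param area optional \code{prediction_area} whose outline is drawn.
#' @param ... passed to [graphics::image()].
#' @export
plot.grid_raster <- function(x, area = NULL, ...) {
  g <- x$geom
  xs <- g$xmin + (seq_len(g$nx) - 0.5) * g$cell_size
  ys <- g$ymin + (seq_len(g$ny) - 0.5) * g$cell_size
  graphics::image(xs, ys, t(raster_matrix(x)), asp = 1,
                  xlab = "x (m)", ylab = "y (m)", main = x$name,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  if (!is.null(area)) {
    graphics::polygon(area$polygon[, 1], area$polygon[, 2], border = "red")
  }
  invisible(x)
}

#' Partial-effect plots of a fitted binomial additive SDM
#'
#' Delegates to mgcv's smooth-term plots (link scale, one panel per smooth).
#'
#' @param x an \code{sdm_gam}.
#' @param ... passed to \code{plot.gam}.
#' @export
plot.sdm_gam <- function(x, ...) {
  if (is.null(x$fit)) stop("model did not converge; nothing to plot")
  graphics::plot(x$fit, pages = 1, ...)
  invisible(x)
}

#' Variable-importance plot of an explanatory forest
#'
#' Horizontal bars of the permutation importance (mean OOB accuracy drop),
#' highest-ranked at the top.
#'
#' @param x an \code{sdm_rf}.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.sdm_rf <- function(x, ...) {
  imp <- x$importance[order(x$importance$importance), ]
  graphics::barplot(imp$importance, names.arg = imp$variable, horiz = TRUE,
                    las = 1, xlab = "mean accuracy drop", ...)
  invisible(x)
}
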