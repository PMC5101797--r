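#' Plot the histogram and the fitted mixture
#'
#' Draws the (density-normalized) histogram of the filtered data with the
#' three weighted component curves and their sum, the usual diagnostic for
#' judging how well the Exp+Exp+Gauss mixture fits the filtered-data
#' histogram. The y axis is square-root scaled by default so the thin vessel
#' lobe stays visible next to the background spike.
#'
#' @param hist an [build_histogram()] result.
#' @param model a [mixture_model()] (or `mixture_fit`).
#' @param sqrt_scale square-root-compress the density axis.
#' @param ... further arguments to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plot_mixture_fit <- function(hist, model, sqrt_scale = TRUE, ...) {
  stopifnot(inherits(hist, "intensity_histogram"),
            inherits(model, "mixture_model"))
  binw <- diff(hist$edges[1:2])
  dens <- hist$counts / (sum(hist$counts) * binw)
  x <- hist$mids
  comp <- component_densities(model, x)
  curves <- cbind(model$w[1] * comp[, 1], model$w[2] * comp[, 2],
                  model$w[3] * comp[, 3])
  mix <- rowSums(curves)
  tr <- if (sqrt_scale) sqrt else identity
  graphics::plot(x, tr(dens), type = "h", col = "grey70",
                 xlab = "intensity", ylab = if (sqrt_scale) "sqrt(density)" else "density",
                 main = "Filtered-data histogram and mixture fit", ...)
  graphics::lines(x, tr(curves[, 1]), col = "dodgerblue3", lwd = 2)
  graphics::lines(x, tr(curves[, 2]), col = "seagreen4", lwd = 2)
  graphics::lines(x, tr(curves[, 3]), col = "firebrick3", lwd = 2)
  graphics::lines(x, tr(mix), col = "black", lwd = 2, lty = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("dodgerblue3", "seagreen4", "firebrick3", "black"),
                   lty = c(1, 1, 1, 2),
                   legend = c("w_E1 f_E1", "w_E2 f_E2", "w_G f_G", "mixture"))
  invisible(NULL)
}

#' Display a Z-axis projection
#'
#' Renders [z_projection()] of a volume as a grey-scale image, the usual
#' qualitative check against the MIP of the original angiogram.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param mode `"max"` (MIP) or `"sum"`.
#' @param ... further arguments to [graphics::image()].
#' @return The projection matrix, invisibly.
#' @export
plot_z_projection <- function(vol, mode = c("max", "sum"), ...) {
  proj <- z_projection(vol, match.arg(mode))
  graphics::image(seq_len(nrow(proj)), seq_len(ncol(proj)), proj,
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  asp = 1, xlab = "x", ylab = "y", useRaster = TRUE, ...)
  invisible(proj)
}
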