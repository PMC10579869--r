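#' Plot methods
#'
#' Best-effort base-graphics views of the analysis objects; every figure
#' has a numeric twin (XVG/CSV) that carries the actual results.
#'
#' @param x the object to plot.
#' @param y ignored.
#' @param ... passed to the underlying base-graphics call.
#' @name plots
NULL

#' @rdname plots
#' @export
setMethod("plot", signature("LabeledSeries", "missing"),
          function(x, y, ...) {
  graphics::plot(x@times, x@values, type = "l", xlab = x@xLabel,
                 ylab = x@yLabel, main = x@title, ...)
  for (e in x@extra) graphics::lines(x@times, e, col = "grey50")
  invisible(x)
})

#' @rdname plots
#' @export
setMethod("plot", signature("FreeEnergySurface", "missing"),
          function(x, y, ...) {
  z <- x@deltaG
  z[!is.finite(z)] <- NA
  xc <- (x@xEdges[-1] + x@xEdges[-length(x@xEdges)]) / 2
  yc <- (x@yEdges[-1] + x@yEdges[-length(x@yEdges)]) / 2
  graphics::image(xc, yc, z, xlab = x@xLabel, ylab = x@yLabel,
                  main = paste0("Free energy landscape (",
                                x@energyUnit, ")"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
})

#' @rdname plots
#' @export
setMethod("plot", signature("DensityEstimate", "missing"),
          function(x, y, ...) {
  mids <- (x@histEdges[-1] + x@histEdges[-length(x@histEdges)]) / 2
  widths <- diff(x@histEdges)
  dens_hist <- x@histCounts / (x@n * widths)
  graphics::plot(x@grid, x@density, type = "n",
                 ylim = c(0, max(x@density, dens_hist)),
                 xlab = "Value", ylab = "Density",
                 main = sprintf("KDE (h = %.3g, %s)", x@bandwidth,
                                x@bwRule), ...)
  graphics::rect(x@histEdges[-length(x@histEdges)], 0, x@histEdges[-1],
                 dens_hist, col = "grey85", border = "grey60")
  graphics::lines(x@grid, x@density, lwd = 2, col = "#CC3333")
  invisible(x)
})

#' @rdname plots
#' @export
setMethod("plot", signature("PMFProfile", "missing"), function(x, y, ...) {
  cov <- is.finite(x@pmf)
  graphics::plot(x@binCenters[cov], x@pmf[cov], type = "l", lwd = 2,
                 xlab = "Reaction coordinate",
                 ylab = paste0("PMF (", x@energyUnit, ")"),
                 main = "Potential of mean force", ...)
  invisible(x)
})
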