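#' Accessors for TrajKit objects
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param x a TrajKit object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("atomInfo", function(x) standardGeneric("atomInfo"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setGeneric("seriesLegend", function(x) standardGeneric("seriesLegend"))
#' @rdname accessors
#' @export
setGeneric("extraColumns", function(x) standardGeneric("extraColumns"))
#' @rdname accessors
#' @export
setGeneric("codeMatrix", function(x) standardGeneric("codeMatrix"))
#' @rdname accessors
#' @export
setGeneric("codeLegend", function(x) standardGeneric("codeLegend"))
#' @rdname accessors
#' @export
setGeneric("deltaG", function(x) standardGeneric("deltaG"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("pmfValues", function(x) standardGeneric("pmfValues"))

#' @rdname accessors
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[2])
#' @rdname accessors
setMethod("coords", "Trajectory", function(x) x@coords)
#' @rdname accessors
setMethod("atomInfo", "Trajectory", function(x) x@atoms)
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
setMethod("seriesTimes", "LabeledSeries", function(x) x@times)
#' @rdname accessors
setMethod("seriesValues", "LabeledSeries", function(x) x@values)
#' @rdname accessors
setMethod("seriesLegend", "LabeledSeries", function(x) x@legend)
#' @rdname accessors
setMethod("extraColumns", "LabeledSeries", function(x) x@extra)
#' @rdname accessors
setMethod("nFrames", "LabeledSeries", function(x) length(x@times))

#' @rdname accessors
setMethod("codeMatrix", "CharMatrix", function(x) x@codes)
#' @rdname accessors
setMethod("codeLegend", "CharMatrix", function(x) x@legend)

#' @rdname accessors
setMethod("deltaG", "FreeEnergySurface", function(x) x@deltaG)
#' @rdname accessors
setMethod("binCounts", "FreeEnergySurface", function(x) x@counts)
#' @rdname accessors
setMethod("pmfValues", "PMFProfile", function(x) x@pmf)

#' Construct a LabeledSeries
#'
#' @param times,values numeric vectors of equal length.
#' @param title,xLabel,yLabel plot metadata strings.
#' @param legend character legends (primary column first).
#' @param extra list of additional numeric columns.
#' @param meta opaque metadata lines to preserve.
#' @return a \linkS4class{LabeledSeries}.
#' @export
LabeledSeries <- function(times, values, title = "", xLabel = "",
                          yLabel = "", legend = character(),
                          extra = list(), meta = character()) {
  new("LabeledSeries", times = as.numeric(times), values = as.numeric(values),
      title = title, xLabel = xLabel, yLabel = yLabel,
      legend = legend, extra = extra, meta = meta)
}

setMethod("show", "LabeledSeries", function(object) {
  cat("LabeledSeries \"", object@title, "\": ", length(object@times),
      " points", sep = "")
  if (length(object@extra)) cat(", ", length(object@extra), " extra column(s)",
                                sep = "")
  cat("\n  x: ", object@xLabel, "  y: ", object@yLabel, "\n", sep = "")
  rng <- range(object@values)
  cat(sprintf("  value range: [%.6g, %.6g]\n", rng[1], rng[2]))
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", nFrames(object), " frame(s) x ", nAtoms(object),
      " atom(s)\n", sep = "")
  if (length(object@times))
    cat(sprintf("  time: %.4g .. %.4g ps\n", object@times[1],
                object@times[length(object@times)]))
  cat("  residues: ", length(unique(object@atoms$resid)), "\n", sep = "")
})

setMethod("show", "CharMatrix", function(object) {
  cat("CharMatrix: ", nrow(object@codes), " row(s) x ", ncol(object@codes),
      " column(s)\n  legend: ",
      paste(sprintf("%s=%s", names(object@legend), object@legend),
            collapse = ", "), "\n", sep = "")
})

setMethod("show", "FreeEnergySurface", function(object) {
  occ <- sum(object@counts > 0)
  cat("FreeEnergySurface: ", nrow(object@counts), " x ", ncol(object@counts),
      " bins (", occ, " occupied), unit ", object@energyUnit, "\n", sep = "")
  cat(sprintf("  max finite dG: %.4g; min bin (%d, %d)\n",
              max(object@deltaG[is.finite(object@deltaG)]),
              object@minBin[1], object@minBin[2]))
})

setMethod("show", "DensityEstimate", function(object) {
  cat(sprintf("DensityEstimate: n = %d, h = %.6g (%s), %d grid points\n",
              object@n, object@bandwidth, object@bwRule,
              length(object@grid)))
})

setMethod("show", "PMFProfile", function(object) {
  cov <- is.finite(object@pmf)
  cat(sprintf(
    "PMFProfile: %d bins (%d covered), %d iteration(s), residual %.3g %s\n",
    length(object@pmf), sum(cov), object@iterations, object@residual,
    object@energyUnit))
  if (length(object@deltaGBind))
    cat(sprintf("  dG_bind = %.4g %s\n", object@deltaGBind,
                object@energyUnit))
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult: ", length(object@sizes), " cluster(s) at cutoff ",
      object@cutoff, " A; sizes: ",
      paste(utils::head(object@sizes, 10), collapse = ", "),
      if (length(object@sizes) > 10) ", ..." else "", "\n", sep = "")
})

setMethod("show", "PCAResult", function(object) {
  ev <- object@eigenvalues
  cat("PCAResult: ", length(ev), " component(s); top eigenvalues (A^2): ",
      paste(sprintf("%.4g", utils::head(ev, 5)), collapse = ", "), "\n",
      sep = "")
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: post-fit RMSD %.6g A\n", object@postFitRMSD))
})

setMethod("show", "UmbrellaWindowSet", function(object) {
  cat("UmbrellaWindowSet: ", length(object@centers), " window(s), centers ",
      sprintf("%.4g .. %.4g", min(object@centers), max(object@centers)),
      "\n", sep = "")
})

setMethod("show", "PullTrace", function(object) {
  cat(sprintf("PullTrace: %d points; peak force %.6g at t = %.6g\n",
              length(object@times), object@peakForce, object@peakTime))
})
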