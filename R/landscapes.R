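# Boltzmann constant, kJ mol^-1 K^-1.
.KB_KJ <- 0.0083144626

#' Free energy landscape by Boltzmann inversion
#'
#' Bins two frame-aligned order-parameter series on a 2D histogram over
#' their observed ranges and converts populations to relative free
#' energies, \eqn{\Delta G_{ij} = -kT \ln(P_{ij}/P_{max})}.  The most
#' probable state is set to exactly zero; every other occupied bin is
#' positive; empty bins are masked with \code{Inf} rather than given a
#' pseudo-count, since the inversion is undefined at zero population.
#' The frame-to-bin map is recorded so minimum-energy frames can be
#' extracted afterwards.
#'
#' @param x,y \linkS4class{LabeledSeries} of the two order parameters,
#'   aligned frame-for-frame (equal length; equal time stamps when both
#'   carry times).
#' @param nBinsX,nBinsY histogram bins per axis, >= 2.
#' @param temperature simulation temperature, Kelvin.
#' @param energyUnit \code{"kT"} (default) or \code{"kJ/mol"}.
#' @return a \linkS4class{FreeEnergySurface}.
#' @export
buildFEL <- function(x, y, nBinsX = 32L, nBinsY = 32L, temperature = 300,
                     energyUnit = c("kT", "kJ/mol")) {
  energyUnit <- match.arg(energyUnit)
  stopifnot(nBinsX >= 2, nBinsY >= 2, temperature > 0)
  xv <- seriesValues(x); yv <- seriesValues(y)
  if (length(xv) != length(yv))
    stop("order parameters are not frame-aligned: lengths ",
         length(xv), " vs ", length(yv))
  if (length(seriesTimes(x)) == length(seriesTimes(y)) &&
      any(seriesTimes(x) != seriesTimes(y)))
    stop("order parameters carry different time stamps")
  xe <- seq(min(xv), max(xv), length.out = nBinsX + 1L)
  ye <- seq(min(yv), max(yv), length.out = nBinsY + 1L)
  bx <- .binIndex(xv, xe); by <- .binIndex(yv, ye)
  counts <- matrix(0L, nBinsX, nBinsY)
  for (f in seq_along(bx)) counts[bx[f], by[f]] <- counts[bx[f], by[f]] + 1L
  kT <- if (energyUnit == "kT") 1 else .KB_KJ * temperature
  cmax <- max(counts)
  dg <- -kT * log(counts / cmax)   # empty bins -> Inf by the math itself
  mb <- which(counts == cmax, arr.ind = TRUE)[1, ]
  dg[mb[1], mb[2]] <- 0            # exact zero at the mode
  new("FreeEnergySurface", xEdges = xe, yEdges = ye, counts = counts,
      deltaG = dg, temperature = temperature, energyUnit = energyUnit,
      frameToBin = cbind(bx, by), minBin = as.integer(mb),
      xLabel = if (nzchar(x@yLabel)) x@yLabel else x@title,
      yLabel = if (nzchar(y@yLabel)) y@yLabel else y@title)
}

# Left-closed equal-width binning; the maximum lands in the last bin.
.binIndex <- function(v, edges) {
  n <- length(edges) - 1L
  if (edges[1] == edges[n + 1L]) return(rep(1L, length(v)))
  pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n)
}

#' Extract the frames of the free-energy minimum (or any) bin
#'
#' Returns up to \code{k} frame indices mapped to the surface's most
#' populated (zero free energy) bin, ordered by frame index; or to an
#' arbitrary user-specified bin via \code{bin = c(i, j)}.
#'
#' @param fes a \linkS4class{FreeEnergySurface} with a frame map.
#' @param k maximum number of frames, >= 1.
#' @param bin optional length-2 bin index overriding the minimum bin.
#' @return integer frame indices (possibly fewer than \code{k}).
#' @export
extractMinEnergyFrames <- function(fes, k = 1L, bin = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (!nrow(fes@frameToBin)) stop("surface carries no frame-to-bin map")
  if (is.null(bin)) bin <- fes@minBin
  hits <- which(fes@frameToBin[, 1] == bin[1] &
                fes@frameToBin[, 2] == bin[2])
  utils::head(sort(hits), k)
}

# ---- bin-count and bandwidth rules ---------------------------------------

.binRules <- list(
  fd = function(v) {
    iqr <- stats::IQR(v)
    if (iqr == 0) return(.binRules$sturges(v))
    max(2L, ceiling(diff(range(v)) / (2 * iqr * length(v)^(-1 / 3))))
  },
  sturges = function(v) max(2L, ceiling(log2(length(v)) + 1)),
  scott = function(v) {
    s <- stats::sd(v)
    if (s == 0) return(.binRules$sturges(v))
    max(2L, ceiling(diff(range(v)) / (3.49 * s * length(v)^(-1 / 3))))
  },
  sqrt = function(v) max(2L, ceiling(sqrt(length(v)))))

.bwRules <- list(
  silverman = function(v) {
    n <- length(v)
    0.9 * min(stats::sd(v), stats::IQR(v) / 1.34) * n^(-1 / 5)
  },
  scott = function(v) 1.06 * stats::sd(v) * length(v)^(-1 / 5))

#' Gaussian kernel density estimate of a trajectory observable
#'
#' Evaluates \eqn{\hat f_h(x) = \frac{1}{nh}\sum_i K((x - x_i)/h)} with a
#' Gaussian kernel on an even grid spanning the data range plus 4h on
#' each side, together with the companion histogram chosen by the bin
#' rule (the histogram-and-density pair the plots show side by side).
#'
#' @param values numeric sample (>= 2 distinct values unless \code{h}
#'   given).
#' @param bandwidthRule \code{"silverman"} (default,
#'   \eqn{h = 0.9\,\min(\hat\sigma, IQR/1.34)\,n^{-1/5}}) or
#'   \code{"scott"}; ignored when \code{h} is supplied.
#' @param h explicit bandwidth (> 0), overriding the rule.
#' @param binRule \code{"fd"} (Freedman-Diaconis, default),
#'   \code{"sturges"}, \code{"scott"} or \code{"sqrt"}; ignored when
#'   \code{nBins} is supplied.
#' @param nBins explicit histogram bin count.
#' @param gridSize evaluation grid points (default 512).
#' @param grid explicit evaluation grid, overriding range and
#'   \code{gridSize}.
#' @return a \linkS4class{DensityEstimate}.
#' @export
kdeEstimate <- function(values, bandwidthRule = c("silverman", "scott"),
                        h = NULL, binRule = c("fd", "sturges", "scott",
                                              "sqrt"),
                        nBins = NULL, gridSize = 512L, grid = NULL) {
  bandwidthRule <- match.arg(bandwidthRule)
  binRule <- match.arg(binRule)
  values <- as.numeric(values)
  n <- length(values)
  if (is.null(h)) {
    if (length(unique(values)) < 2)
      stop("zero variance sample: supply an explicit bandwidth h")
    h <- .bwRules[[bandwidthRule]](values)
    bwName <- bandwidthRule
  } else bwName <- "explicit"
  if (h <= 0) stop("bandwidth must be > 0")
  if (is.null(grid))
    grid <- seq(min(values) - 4 * h, max(values) + 4 * h,
                length.out = gridSize)
  dens <- vapply(grid, function(g)
    sum(stats::dnorm((g - values) / h)), numeric(1)) / (n * h)
  if (is.null(nBins)) {
    nBins <- if (n >= 2 && length(unique(values)) >= 2)
      .binRules[[binRule]](values) else 1L
    binName <- binRule
  } else binName <- "explicit"
  edges <- seq(min(values), max(values), length.out = nBins + 1L)
  if (edges[1] == edges[nBins + 1L])
    edges <- c(edges[1] - h, edges[1] + h)
  cnt <- tabulate(.binIndex(values, edges), length(edges) - 1L)
  new("DensityEstimate", grid = grid, density = dens, bandwidth = h,
      n = n, histEdges = edges, histCounts = as.integer(cnt),
      kernel = "gaussian", binRule = binName, bwRule = bwName)
}

#' Comparative KDE of several datasets on a common grid
#'
#' Each sample keeps its own bandwidth (rule or explicit) and is
#' normalised independently; all densities are evaluated on one shared
#' grid spanning the union of the sample ranges, padded by 4 times the
#' largest bandwidth.
#'
#' @param samples named list of numeric vectors.
#' @param gridSize shared grid size.
#' @param ... passed to \code{\link{kdeEstimate}} (e.g. bandwidthRule, h).
#' @return named list of \linkS4class{DensityEstimate} on the same grid.
#' @export
kdeCompare <- function(samples, gridSize = 512L, ...) {
  stopifnot(is.list(samples), length(samples) >= 1)
  pre <- lapply(samples, function(v) kdeEstimate(v, gridSize = 8L, ...))
  hmax <- max(vapply(pre, function(d) d@bandwidth, numeric(1)))
  rng <- range(unlist(samples))
  grid <- seq(rng[1] - 4 * hmax, rng[2] + 4 * hmax, length.out = gridSize)
  lapply(stats::setNames(seq_along(samples), names(samples)), function(i)
    kdeEstimate(samples[[i]], grid = grid, ...))
}
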