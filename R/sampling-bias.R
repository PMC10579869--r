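#' Join steered-MD pull force and position traces
#'
#' Joins the force and COM-position series on common times (exact match,
#' or nearest within half the median sampling interval), computes the
#' displacement relative to the first joined point, and reports the peak
#' force and when it occurs — the force-vs-time, displacement-vs-time and
#' force-vs-displacement views of a pulling run.
#'
#' @param forceSeries \linkS4class{LabeledSeries}, force (kJ/mol/nm).
#' @param positionSeries \linkS4class{LabeledSeries}, COM distance (nm).
#' @return a \linkS4class{PullTrace}.
#' @export
pullAnalysis <- function(forceSeries, positionSeries) {
  tf <- seriesTimes(forceSeries); tp <- seriesTimes(positionSeries)
  if (!length(tf) || !length(tp)) stop("empty pull series")
  if (min(tf) > max(tp) || min(tp) > max(tf))
    stop("force and position traces have no overlapping times")
  half_dt <- stats::median(diff(sort(unique(tp)))) / 2
  if (!is.finite(half_dt)) half_dt <- 0
  near <- vapply(tf, function(t) {
    j <- which.min(abs(tp - t))
    if (abs(tp[j] - t) <= half_dt) j else NA_integer_
  }, integer(1))
  keep <- !is.na(near)
  if (!any(keep))
    stop("no force/position time pairs match within half a sampling interval")
  t <- tf[keep]
  force <- seriesValues(forceSeries)[keep]
  pos <- seriesValues(positionSeries)[near[keep]]
  dedup <- !duplicated(t)
  t <- t[dedup]; force <- force[dedup]; pos <- pos[dedup]
  disp <- pos - pos[1]
  pk <- which.max(force)
  new("PullTrace", times = t, force = force, displacement = disp,
      peakForce = force[pk], peakTime = t[pk])
}

#' Select umbrella-sampling starting frames by COM-distance spacing
#'
#' Greedy walk along the pulling trajectory: the first frame is always
#' selected; thereafter the frame whose COM distance is nearest to (last
#' selected distance + spacing) is taken, ties going to the earlier
#' frame, until the target would pass the final frame's distance.  When
#' the spacing exceeds the whole distance range only the first and last
#' frames are returned, with a warning.
#'
#' @param comDistance \linkS4class{LabeledSeries} of the per-frame COM
#'   distance (the pulling coordinate).
#' @param spacing desired window spacing, same length unit, > 0.
#' @return list: \code{frames} (indices), \code{centers} (achieved
#'   distances), \code{ideal} (target distances), \code{deviation}
#'   (|achieved - ideal| per window).
#' @export
selectWindows <- function(comDistance, spacing) {
  stopifnot(spacing > 0)
  d <- seriesValues(comDistance)
  n <- length(d)
  if (n < 2) stop("window selection needs at least 2 frames")
  frames <- 1L
  ideal <- d[1]
  target <- d[1] + spacing
  d_end <- d[n]
  while (target <= d_end + 1e-12) {
    cand <- which.min(abs(d - target))   # first index wins ties
    if (cand == frames[length(frames)]) break  # no progress possible
    frames <- c(frames, cand)
    ideal <- c(ideal, target)
    target <- d[cand] + spacing
  }
  warned <- FALSE
  if (length(frames) == 1L) {
    frames <- c(frames, n)
    ideal <- c(ideal, d[n])
    warning("spacing ", spacing, " exceeds the sampled distance range; ",
            "returning only the first and last frames")
    warned <- TRUE
  }
  list(frames = frames, centers = d[frames], ideal = ideal,
       deviation = abs(d[frames] - ideal), degenerate = warned)
}

#' WHAM: unbiased PMF from umbrella windows
#'
#' Self-consistent iteration of the weighted histogram analysis method
#' over a shared reaction-coordinate histogram (equal-width bins spanning
#' the union of the window sample ranges):
#' \deqn{P(\xi_b) = \frac{\sum_i n_{ib}}{\sum_i N_i \exp((F_i - w_i(\xi_b))/kT)},
#'       \qquad F_i = -kT \ln \sum_b P(\xi_b) e^{-w_i(\xi_b)/kT},}
#' with the harmonic bias \eqn{w_i(\xi) = \frac{1}{2} k_i (\xi - c_i)^2},
#' iterated until the largest change in any \eqn{F_i} drops below
#' \code{tolerance}.  The gauge is fixed by \eqn{F_1 = 0}.  The PMF is
#' \eqn{-kT \ln P}, shifted so its minimum over covered bins is 0; bins
#' with no samples are masked (\code{Inf}).  Adjacent windows whose
#' histograms share no occupied bin trigger a coverage warning.
#'
#' Energies are in kT throughout; request kJ/mol to scale the output by
#' \eqn{k_B T}.
#'
#' @param windows an \linkS4class{UmbrellaWindowSet} (spring constants in
#'   kT/length^2).
#' @param nBins histogram bins over the union support (default 200).
#' @param tolerance convergence threshold on max |dF_i|, kT (default 1e-6).
#' @param maxIterations iteration cap (default 100000).
#' @param temperature Kelvin, used only for kJ/mol output.
#' @param energyUnit \code{"kT"} (default) or \code{"kJ/mol"}.
#' @return a \linkS4class{PMFProfile}.
#' @export
wham <- function(windows, nBins = 200L, tolerance = 1e-6,
                 maxIterations = 100000L, temperature = 300,
                 energyUnit = c("kT", "kJ/mol")) {
  energyUnit <- match.arg(energyUnit)
  stopifnot(is(windows, "UmbrellaWindowSet"), nBins >= 2)
  nw <- length(windows@centers)
  rng <- range(unlist(windows@samples))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = nBins + 1L)
  centers_b <- (edges[-1] + edges[-length(edges)]) / 2
  # n_ib: windows x bins counts
  nib <- t(vapply(windows@samples, function(s)
    tabulate(.binIndex(s, edges), nBins), numeric(nBins)))
  Ni <- rowSums(nib)
  # adjacent-window overlap diagnostic, in center order
  ord <- order(windows@centers)
  for (k in seq_len(nw - 1)) {
    if (!any(nib[ord[k], ] > 0 & nib[ord[k + 1], ] > 0))
      warning("umbrella windows ", ord[k], " and ", ord[k + 1],
              " (centers ", windows@centers[ord[k]], ", ",
              windows@centers[ord[k + 1]],
              ") share no occupied histogram bin")
  }
  # bias energies w_i(xi_b), kT: windows x bins
  W <- 0.5 * windows@springK *
    (matrix(centers_b, nw, nBins, byrow = TRUE) - windows@centers)^2
  sum_counts <- colSums(nib)
  covered <- sum_counts > 0
  if (!any(covered)) stop("no samples fall inside the histogram support")
  eW <- exp(-W)
  Fi <- rep(0, nw)
  residual <- Inf
  history <- numeric(0)
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    denom <- colSums((Ni * exp(Fi)) * eW)   # recycles over rows
    P <- sum_counts / denom
    Fnew <- -log(pmax(eW %*% P, .Machine$double.xmin))[, 1]
    Fnew <- Fnew - Fnew[1]                  # gauge: F_1 = 0
    residual <- max(abs(Fnew - Fi))
    Fi <- Fnew
    history <- c(history, residual)
    if (residual < tolerance) break
  }
  if (residual >= tolerance)
    stop("WHAM did not converge in ", maxIterations,
         " iterations (residual ", signif(residual, 3), " kT)")
  denom <- colSums((Ni * exp(Fi)) * eW)
  P <- sum_counts / denom
  pmf <- rep(Inf, nBins)
  pmf[covered] <- -log(P[covered])
  pmf[covered] <- pmf[covered] - min(pmf[covered])
  scale <- if (energyUnit == "kT") 1 else .KB_KJ * temperature
  new("PMFProfile", binCenters = centers_b, pmf = pmf * scale,
      windowF = Fi * scale, iterations = iter, residual = residual,
      residualHistory = history, energyUnit = energyUnit)
}

#' Binding free energy from a PMF plateau
#'
#' The unbinding cost is the mean PMF over the terminal fraction of the
#' covered reaction coordinate (default the last 10% of covered bins),
#' relative to the PMF minimum at 0; the binding free energy is its
#' negative (binding releases what unbinding costs).
#'
#' @param pmf a \linkS4class{PMFProfile}.
#' @param plateauFraction terminal fraction of covered bins to average
#'   (default 0.1).
#' @return the input profile with \code{deltaGBind} set; retrieve the
#'   numbers via \code{attr(, "summary")}: \code{unbindingCost},
#'   \code{deltaGBind}, \code{plateauBins}.
#' @export
bindingEnergy <- function(pmf, plateauFraction = 0.1) {
  stopifnot(is(pmf, "PMFProfile"), plateauFraction > 0,
            plateauFraction <= 1)
  cov <- which(is.finite(pmf@pmf))
  if (length(cov) < 2) stop("PMF covers too few bins")
  if (which.min(pmf@pmf[cov]) == length(cov))
    stop("PMF has no region beyond its global minimum")
  k <- max(1L, round(plateauFraction * length(cov)))
  tail_bins <- cov[seq.int(length(cov) - k + 1L, length(cov))]
  cost <- mean(pmf@pmf[tail_bins])
  pmf@deltaGBind <- -cost
  attr(pmf, "summary") <- list(unbindingCost = cost, deltaGBind = -cost,
                               plateauBins = tail_bins)
  pmf
}
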