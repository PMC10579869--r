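#' Average an analysis series over replica simulations
#'
#' Replicas are aligned onto the first series' time grid by linear
#' interpolation within each replica's own time range (no extrapolation);
#' the per-point mean and sample (n-1) standard deviation are computed
#' over the replicas covering that time, and points covered by fewer than
#' two replicas are flagged.
#'
#' @param seriesList list of >= 2 \linkS4class{LabeledSeries}, each with
#'   >= 2 points.
#' @return list: \code{mean} and \code{sd} (\linkS4class{LabeledSeries}
#'   on the first replica's grid, with the other two statistics attached
#'   as extra columns on \code{mean}), \code{nUsed} (integer per point),
#'   \code{underCovered} (logical per point).
#' @export
averageSeries <- function(seriesList) {
  if (length(seriesList) < 2)
    stop("replica averaging needs at least 2 series")
  for (s in seriesList)
    if (nFrames(s) < 2) stop("every replica needs at least 2 points")
  grid <- seriesTimes(seriesList[[1]])
  r1 <- range(grid)
  vals <- vapply(seriesList, function(s) {
    rs <- range(seriesTimes(s))
    if (rs[1] > r1[2] || rs[2] < r1[1])
      stop("replica time ranges are disjoint: [", rs[1], ", ", rs[2],
           "] vs [", r1[1], ", ", r1[2], "]")
    stats::approx(seriesTimes(s), seriesValues(s), xout = grid,
                  rule = 1)$y
  }, numeric(length(grid)))
  vals <- rbind(vals)  # keep matrix shape for length-1 grids
  n_used <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  sdev <- apply(vals, 1, stats::sd, na.rm = TRUE)
  sdev[n_used < 2] <- NA_real_
  first <- seriesList[[1]]
  mean_s <- LabeledSeries(grid, mu,
    title = paste0(first@title, " (replica mean)"),
    xLabel = first@xLabel, yLabel = first@yLabel,
    legend = c("mean", "sd", "n"),
    extra = list(sd = sdev, n = as.numeric(n_used)))
  sd_s <- LabeledSeries(grid, ifelse(is.na(sdev), 0, sdev),
    title = paste0(first@title, " (replica sd)"),
    xLabel = first@xLabel, yLabel = first@yLabel, legend = "sd")
  list(mean = mean_s, sd = sd_s, nUsed = n_used,
       underCovered = n_used < 2)
}
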