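#' Principal component analysis of atomic coordinates
#'
#' Frames are superposed onto the time-average structure (one refinement
#' pass), then the covariance of the 3N-dimensional coordinate vectors is
#' diagonalised.  Projections are the centered coordinates dotted with the
#' eigenvectors; the leading components serve as order parameters for the
#' free energy landscape.  The sample covariance uses the n-1 denominator,
#' so the projections' sample covariance is exactly diagonal with the
#' eigenvalues on its diagonal.
#'
#' @param traj a \linkS4class{Trajectory} with >= 2 frames.
#' @param selection see \code{\link{selectAtoms}}; default backbone.
#' @param massWeighted weight coordinates by sqrt(mass) before the
#'   covariance (gmx covar-style); default FALSE.
#' @param nComponents components to retain (default all).
#' @return a \linkS4class{PCAResult}; eigenvalues in Angstrom^2 (or
#'   amu Angstrom^2 when mass-weighted).
#' @export
trajectoryPCA <- function(traj, selection = "backbone",
                          massWeighted = FALSE, nComponents = NULL) {
  if (nFrames(traj) < 2)
    stop("PCA needs at least 2 frames (covariance is zero otherwise)")
  idx <- selectAtoms(traj, selection)
  a <- atomInfo(traj)[idx, ]
  w <- a$mass
  m0 <- apply(traj@coords[, idx, , drop = FALSE], c(2, 3), mean)
  aligned <- .alignFrames(traj, idx, m0, w)
  m1 <- apply(aligned, c(2, 3), mean)
  nf <- dim(aligned)[1]
  # frame x 3N matrix, atom-major (x1 y1 z1 x2 ...)
  X <- t(vapply(seq_len(nf), function(f) as.vector(t(aligned[f, , ])),
                numeric(3 * length(idx))))
  X <- sweep(X, 2, as.vector(t(m1)))
  if (massWeighted) X <- sweep(X, 2, rep(sqrt(w), each = 3), "*")
  C <- crossprod(X) / (nf - 1)
  eg <- eigen(C, symmetric = TRUE)
  k <- if (is.null(nComponents)) ncol(eg$vectors)
       else min(nComponents, ncol(eg$vectors))
  new("PCAResult",
      eigenvalues = eg$values[seq_len(k)],
      eigenvectors = eg$vectors[, seq_len(k), drop = FALSE],
      projections = X %*% eg$vectors[, seq_len(k), drop = FALSE],
      meanStructure = m1)
}

#' Pairwise post-superposition RMSD matrix
#'
#' @inheritParams trajectoryPCA
#' @param massWeighted mass-weight the fit and the RMSD.
#' @return symmetric n_frames x n_frames matrix, Angstrom.
#' @export
pairwiseRMSD <- function(traj, selection = "backbone",
                         massWeighted = TRUE) {
  idx <- selectAtoms(traj, selection)
  w <- if (massWeighted) atomInfo(traj)$mass[idx] else NULL
  nf <- nFrames(traj)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    xi <- traj@coords[i, idx, , drop = TRUE]
    for (j in seq.int(i + 1, nf)) {
      D[i, j] <- D[j, i] <-
        kabschSuperpose(traj@coords[j, idx, , drop = TRUE], xi,
                        w)@postFitRMSD
    }
  }
  D
}

#' GROMOS (Daura) conformational clustering
#'
#' Iteratively, the frame with the most neighbours within \code{cutoff}
#' (pairwise post-fit RMSD) becomes a cluster center; it and its
#' neighbours form a cluster and are removed; the procedure repeats until
#' no frames remain.  Ties are broken by the lowest frame index.  Clusters
#' are numbered by decreasing size, then by center index, so the result
#' is deterministic given the distance matrix.
#'
#' @param x a \linkS4class{Trajectory} or a precomputed symmetric distance
#'   matrix.
#' @param cutoff RMSD cutoff, Angstrom, > 0.
#' @param selection used when \code{x} is a Trajectory.
#' @return a \linkS4class{ClusterResult}.
#' @export
gromosCluster <- function(x, cutoff, selection = "backbone") {
  stopifnot(cutoff > 0)
  D <- if (is(x, "Trajectory")) pairwiseRMSD(x, selection) else as.matrix(x)
  n <- nrow(D)
  if (!n) stop("empty trajectory: nothing to cluster")
  remaining <- rep(TRUE, n)
  assignment <- integer(n)
  centers <- integer(); sizes <- integer()
  adj <- D <= cutoff
  k <- 0L
  while (any(remaining)) {
    live <- which(remaining)
    counts <- vapply(live, function(i) sum(adj[i, live]), 1L)
    center <- live[which.max(counts)]  # which.max takes the first = lowest index
    members <- live[adj[center, live]]
    k <- k + 1L
    assignment[members] <- k
    centers[k] <- center
    sizes[k] <- length(members)
    remaining[members] <- FALSE
  }
  ord <- order(-sizes, centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  new("ClusterResult", assignment = relabel[assignment],
      centers = centers[ord], sizes = sizes[ord], cutoff = cutoff)
}

#' Cluster membership over time as a series
#'
#' The time-vs-cluster-id companion to the size distribution: which
#' cluster each frame belongs to, in cluster-size order.
#'
#' @param clusters a \linkS4class{ClusterResult}.
#' @param times optional frame times.
#' @return a \linkS4class{LabeledSeries}.
#' @export
clusterIdSeries <- function(clusters, times = NULL) {
  n <- length(clusters@assignment)
  t <- if (is.null(times)) seq_len(n) - 1 else times
  LabeledSeries(t, clusters@assignment, title = "Cluster membership",
                xLabel = if (is.null(times)) "Frame" else "Time (ps)",
                yLabel = "Cluster id", legend = "cluster")
}
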