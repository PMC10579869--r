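# Shared fixture builders and independent oracles used across the suite.

# A bare Trajectory from an explicit coordinate array (frames x atoms x 3).
makeTraj <- function(xyz, element = "C", name = NULL, resid = NULL,
                     mass = NULL) {
  na <- dim(xyz)[2]
  element <- rep(element, length.out = na)
  if (is.null(name)) name <- element
  if (is.null(resid)) resid <- seq_len(na)
  atoms <- data.frame(serial = seq_len(na), name = rep(name, length.out = na),
                      element = element, resid = rep(resid, length.out = na),
                      resname = "UNK", chain = "A",
                      mass = if (is.null(mass))
                        c(H = 1.008, C = 12.011, N = 14.007,
                          O = 15.999)[element]
                      else rep(mass, length.out = na),
                      stringsAsFactors = FALSE)
  new("Trajectory", coords = xyz, atoms = atoms, times = numeric())
}

oneFrame <- function(mat) array(mat, dim = c(1, nrow(mat), 3))

# Stack n x 3 frame matrices into a frames x atoms x 3 array.
stackFrames <- function(...) {
  frames <- list(...)
  xyz <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) xyz[f, , ] <- frames[[f]]
  xyz
}

# Independent RMSD oracle: exhaustive Euler-angle grid search with
# successive local refinement around the best cell.
gridRotationRMSD <- function(mobile, reference, n = 16, passes = 4) {
  cmM <- colMeans(mobile); cmR <- colMeans(reference)
  X <- sweep(mobile, 2, cmM); Y <- sweep(reference, 2, cmR)
  evalR <- function(a, b, g) {
    Rz1 <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rz2 <- rbind(c(cos(g), -sin(g), 0), c(sin(g), cos(g), 0), c(0, 0, 1))
    sqrt(mean(rowSums((X %*% (Rz1 %*% Ry %*% Rz2) - Y)^2)))
  }
  center <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)          # half-widths of the full Euler box
  best <- Inf; bestAng <- center
  for (p in seq_len(passes)) {
    as <- seq(center[1] - span[1], center[1] + span[1], length.out = n)
    bs <- seq(center[2] - span[2], center[2] + span[2], length.out = n)
    gs <- seq(center[3] - span[3], center[3] + span[3], length.out = n)
    for (a in as) for (b in bs) for (g in gs) {
      v <- evalR(a, b, g)
      if (v < best) { best <- v; bestAng <- c(a, b, g) }
    }
    center <- bestAng
    span <- span * 2.5 / (n - 1)     # zoom in around the best cell
  }
  best
}

# Independent Daura clustering oracle operating on a distance matrix.
dauraOracle <- function(D, cutoff) {
  n <- nrow(D)
  remaining <- seq_len(n)
  assignment <- integer(n); centers <- integer(); sizes <- integer()
  k <- 0L
  while (length(remaining)) {
    counts <- vapply(remaining, function(i)
      sum(D[i, remaining] <= cutoff), 1L)
    center <- remaining[which.max(counts)]
    members <- remaining[D[center, remaining] <= cutoff]
    k <- k + 1L
    assignment[members] <- k; centers[k] <- center
    sizes[k] <- length(members)
    remaining <- setdiff(remaining, members)
  }
  ord <- order(-sizes, centers)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  list(assignment = relabel[assignment], centers = centers[ord],
       sizes = sizes[ord])
}

# A random proper rotation for invariance checks.
randomRot <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform to every frame of a trajectory.
rigidTransform <- function(traj, R, t) {
  for (f in seq_len(nFrames(traj)))
    traj@coords[f, , ] <- sweep(traj@coords[f, , , drop = TRUE] %*% R,
                                2, t, "+")
  traj
}

# Hand-rolled XVG text for parser tests.
writeLinesTmp <- function(lines) {
  f <- tempfile(fileext = ".xvg")
  writeLines(lines, f)
  f
}
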