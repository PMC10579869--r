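#' Analytic potentials for the synthetic generators
#'
#' Constructors for the ground-truth potentials (energies in kT) that the
#' Boltzmann sampler and umbrella-window generator draw from.
#'
#' @param k spring constant, kT per length^2 (> 0).
#' @param dimension 1 or 2.
#' @param barrier barrier height at the midpoint, kT.
#' @param separation distance between the two minima.
#' @param x,u tabulated abscissae and energies (kT); linearly interpolated.
#' @return a \linkS4class{PotentialSpec}.
#' @export
harmonicPotential <- function(k = 1, dimension = 1)
  new("PotentialSpec", form = "harmonic", params = list(k = k),
      dimension = dimension)

#' @rdname harmonicPotential
#' @export
doubleWellPotential <- function(barrier = 4, separation = 4)
  new("PotentialSpec", form = "double_well",
      params = list(barrier = barrier, separation = separation),
      dimension = 1)

#' @rdname harmonicPotential
#' @export
tabulatedPotential <- function(x, u)
  new("PotentialSpec", form = "tabulated", params = list(x = x, u = u),
      dimension = 1)

#' @rdname harmonicPotential
#' @export
flatPotential <- function(dimension = 1)
  new("PotentialSpec", form = "flat", params = list(), dimension = dimension)

#' Evaluate a PotentialSpec (kT units)
#'
#' The double well is \eqn{B((x/a)^2 - 1)^2} with half-separation
#' \eqn{a}, giving minima at \eqn{\pm a} and barrier \eqn{B} at 0.
#' Tabulated potentials are linearly interpolated and infinite outside
#' their domain.
#'
#' @param potential a \linkS4class{PotentialSpec}.
#' @param x numeric vector (1D) or n x 2 matrix (2D).
#' @return energies in kT.
#' @export
potentialEnergy <- function(potential, x) {
  p <- potential@params
  if (potential@dimension == 2) {
    x <- rbind(x)
    switch(potential@form,
      harmonic = 0.5 * p$k * rowSums(x^2),
      flat = rep(0, nrow(x)),
      stop("2D form not supported: ", potential@form))
  } else {
    switch(potential@form,
      harmonic = 0.5 * p$k * x^2,
      flat = rep(0, length(x)),
      double_well = {
        a <- p$separation / 2
        p$barrier * ((x / a)^2 - 1)^2
      },
      tabulated = {
        u <- stats::approx(p$x, p$u, xout = x, rule = 1)$y
        u[is.na(u)] <- Inf
        u
      })
  }
}

# Proposal width heuristic: ~2.4 sigma of the target gives 40-50%
# Metropolis acceptance for near-Gaussian targets.
.proposalWidth <- function(potential, temperatureKT) {
  p <- potential@params
  switch(potential@form,
    harmonic = 2.4 * sqrt(temperatureKT / p$k),
    double_well = p$separation / 2,
    tabulated = diff(range(p$x)) / 10,
    flat = 1)
}

#' Metropolis Boltzmann sampler
#'
#' Draws samples from \eqn{\exp(-U/kT)} by Metropolis Monte Carlo with a
#' Gaussian proposal.  Defaults: burn-in 1,000 steps, thinning 10,
#' proposal width ~2.4 times the target's scale; all overridable.  The
#' seed fixes the stream exactly.
#'
#' @param potential a \linkS4class{PotentialSpec}.
#' @param nSamples number of (post-thinning) samples, >= 1.
#' @param temperatureKT temperature in kT units of the potential (1 =
#'   the potential's native temperature).
#' @param seed integer RNG seed.
#' @param burnIn,thin,step sampler constants.
#' @param bias optional function(x) adding a bias energy in kT (used by
#'   the umbrella-window generator).
#' @param start starting point (defaults to the origin).
#' @return numeric vector (1D) or nSamples x 2 matrix (2D).
#' @export
sampleBoltzmann <- function(potential, nSamples, temperatureKT = 1,
                            seed = 1, burnIn = 1000L, thin = 10L,
                            step = NULL, bias = NULL, start = NULL) {
  stopifnot(nSamples >= 1)
  d <- potential@dimension
  if (is.null(step)) step <- .proposalWidth(potential, temperatureKT)
  energy <- function(x) {
    u <- potentialEnergy(potential, x)
    if (!is.null(bias)) u <- u + bias(x)
    u
  }
  x <- if (is.null(start)) rep(0, d) else start
  u <- energy(if (d == 2) rbind(x) else x)
  if (!is.finite(u)) stop("potential is non-finite at the starting point")
  n_steps <- burnIn + nSamples * thin
  out <- matrix(NA_real_, nSamples, d)
  set.seed(seed)
  # pre-drawn innovations keep the loop lean and the stream reproducible
  prop <- matrix(stats::rnorm(n_steps * d, sd = step), n_steps, d)
  lu <- log(stats::runif(n_steps))
  kept <- 0L
  for (s in seq_len(n_steps)) {
    xn <- x + prop[s, ]
    un <- energy(if (d == 2) rbind(xn) else xn)
    if (is.finite(un) && lu[s] <= (u - un) / temperatureKT) {
      x <- xn; u <- un
    }
    if (s > burnIn && (s - burnIn) %% thin == 0L) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  if (d == 1) drop(out) else out
}

#' Generate a fluctuating toy trajectory
#'
#' A reference extended-chain geometry (pseudo-C-alpha spacing 3.8 A)
#' plus independent isotropic Gaussian displacements of the stated
#' amplitude per atom per frame.  With \code{rigidMotion = TRUE} each
#' frame additionally receives a random rigid rotation + translation, so
#' raw coordinates differ even at amplitude 0 while any superposed metric
#' is unchanged.
#'
#' @param nAtoms,nFrames counts, >= 1.
#' @param amplitude per-coordinate Gaussian sigma, Angstrom, >= 0.
#' @param seed integer RNG seed.
#' @param rigidMotion add a random rigid transform per frame.
#' @param dt frame spacing, ps.
#' @return a \linkS4class{Trajectory} of CA pseudo-atoms (one per residue).
#' @export
makeFluctuatingTrajectory <- function(nAtoms, nFrames, amplitude = 0.5,
                                      seed = 1, rigidMotion = FALSE,
                                      dt = 10) {
  stopifnot(nAtoms >= 1, nFrames >= 1, amplitude >= 0)
  set.seed(seed)
  i <- seq_len(nAtoms)
  # gently kinked chain: never collinear for nAtoms >= 3
  ref <- cbind(3.8 * i, 1.5 * sin(0.7 * i), 1.5 * cos(0.7 * i))
  xyz <- array(NA_real_, c(nFrames, nAtoms, 3))
  for (f in seq_len(nFrames)) {
    fr <- ref + matrix(stats::rnorm(nAtoms * 3, sd = amplitude), nAtoms, 3)
    if (rigidMotion) {
      R <- .randomRotation()
      fr <- fr %*% R + matrix(stats::runif(3, -10, 10), nAtoms, 3,
                              byrow = TRUE)
    }
    xyz[f, , ] <- fr
  }
  atoms <- data.frame(
    serial = i, name = "CA", element = "C", resid = i, resname = "ALA",
    chain = "A", mass = 12.011, stringsAsFactors = FALSE)
  new("Trajectory", coords = xyz, atoms = atoms,
      times = dt * (seq_len(nFrames) - 1))
}

.randomRotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate harmonically biased umbrella windows
#'
#' For each restraint center \eqn{c_i}, Metropolis samples are drawn from
#' \eqn{\exp(-(U(\xi) + \frac{1}{2} k (\xi - c_i)^2)/kT)}; restraint
#' parameters are stored with the samples.  Window overlap is not checked
#' here — the WHAM solver diagnoses gaps.
#'
#' @param potential a 1D \linkS4class{PotentialSpec}.
#' @param centers restraint centers (>= 2).
#' @param springK spring constant, kT/length^2, > 0.
#' @param nPerWindow samples per window.
#' @param temperatureKT temperature, kT units.
#' @param seed integer seed; window i uses stream seed + i - 1.
#' @param ... further arguments to \code{\link{sampleBoltzmann}}.
#' @return an \linkS4class{UmbrellaWindowSet}.
#' @export
makeUmbrellaWindows <- function(potential, centers, springK, nPerWindow,
                                temperatureKT = 1, seed = 1, ...) {
  stopifnot(length(centers) >= 2, springK > 0)
  samples <- lapply(seq_along(centers), function(i) {
    ci <- centers[i]
    sampleBoltzmann(potential, nPerWindow, temperatureKT,
                    seed = seed + i - 1L,
                    bias = function(x) 0.5 * springK * (x - ci)^2,
                    step = 2.4 * sqrt(temperatureKT / springK),
                    start = ci, ...)
  })
  new("UmbrellaWindowSet", centers = as.numeric(centers),
      springK = rep(springK, length(centers)), samples = samples)
}

#' Generate a random secondary-structure code matrix
#'
#' Cells are drawn independently from \code{alphabet} with the given
#' weights.  When the matrix has at least as many cells as the alphabet
#' has codes, every code is guaranteed to appear at least once (the first
#' cells, in random positions, are overwritten with one of each code).
#'
#' @param nResidues,nFrames matrix dimensions.
#' @param alphabet character codes; default is the 7-type DSSP timeline
#'   alphabet H, G, I, E, B, T, S (coil \code{"C"}/\code{"~"} cells are
#'   also understood downstream).
#' @param weights sampling weights, recycled/normalised.
#' @param seed integer RNG seed.
#' @param legend optional named character legend; defaults to DSSP names.
#' @return a \linkS4class{CharMatrix}.
#' @export
makeSSMatrix <- function(nResidues, nFrames,
                         alphabet = c("H", "G", "I", "E", "B", "T", "S"),
                         weights = NULL, seed = 1, legend = NULL) {
  stopifnot(nResidues >= 1, nFrames >= 1, length(alphabet) >= 1)
  set.seed(seed)
  if (is.null(weights)) weights <- rep(1, length(alphabet))
  weights <- weights / sum(weights)
  cells <- sample(alphabet, nResidues * nFrames, replace = TRUE,
                  prob = weights)
  if (nResidues * nFrames >= length(alphabet)) {
    pos <- sample(nResidues * nFrames, length(alphabet))
    cells[pos] <- alphabet
  }
  m <- matrix(cells, nResidues, nFrames)
  if (is.null(legend)) {
    full <- c(H = "A-Helix", G = "3-Helix", I = "5-Helix", E = "B-Sheet",
              B = "B-Bridge", T = "Turn", S = "Bend", C = "Coil",
              "~" = "Coil")
    legend <- full[alphabet]
    legend[is.na(legend)] <- alphabet[is.na(legend)]
    names(legend) <- alphabet
  }
  new("CharMatrix", codes = m, rowLabels = seq_len(nResidues),
      colLabels = seq_len(nFrames), legend = legend,
      colors = stats::setNames(grDevices::rainbow(length(alphabet)),
                               alphabet),
      title = "Secondary structure")
}
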