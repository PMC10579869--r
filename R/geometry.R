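# Bondi-style van der Waals radii (Angstrom) for SASA.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                NA. = 2.27, MG = 1.73, K = 2.75, CA = 2.31, ZN = 1.39,
                FE = 1.95, MN = 1.95, CU = 1.40, SE = 1.90)

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Resolve an atom selection on a trajectory
#'
#' Accepts integer indices, a logical mask, or one of the keywords
#' \code{"all"}, \code{"backbone"} (N, CA, C, O), \code{"calpha"},
#' \code{"heavy"} (non-hydrogen), \code{"protein"} (alias of all here).
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param selection keyword, indices, or logical mask.
#' @return integer atom indices.
#' @export
selectAtoms <- function(traj, selection = "all") {
  a <- atomInfo(traj)
  idx <- if (is.character(selection)) {
    switch(selection,
      all = , protein = seq_len(nrow(a)),
      backbone = which(a$name %in% .BACKBONE_NAMES),
      calpha = which(a$name == "CA"),
      heavy = which(a$element != "H"),
      stop("unknown selection keyword: ", selection))
  } else if (is.logical(selection)) which(selection)
  else as.integer(selection)
  if (!length(idx)) stop("selection matches no atoms")
  idx
}

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the weighted RMSD
#' of \code{mobile} onto \code{reference} via the SVD of the weighted
#' cross-covariance, with the reflection branch corrected so the rotation
#' determinant is +1.  Apply as \code{mobile \%*\% rotation + translation}
#' (translation recycled per row).
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @param weights per-atom weights (e.g. masses); uniform when NULL.
#' @return a \linkS4class{Superposition}.
#' @export
kabschSuperpose <- function(mobile, reference, weights = NULL) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  n <- nrow(mobile)
  if (n < 3 || nrow(reference) != n)
    stop("superposition needs equal atom counts >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cmM <- colSums(mobile * w); cmR <- colSums(reference * w)
  X <- sweep(mobile, 2, cmM); Y <- sweep(reference, 2, cmR)
  H <- crossprod(X * w, Y)
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1))
    stop("degenerate (collinear) configuration: superposition undefined")
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- X %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  new("Superposition", rotation = R,
      translation = as.numeric(cmR - cmM %*% R), postFitRMSD = rmsd)
}

#' Apply a Superposition to coordinates
#' @param sp a \linkS4class{Superposition}.
#' @param x n x 3 coordinates.
#' @return transformed n x 3 coordinates.
#' @export
applySuperposition <- function(sp, x)
  sweep(rbind(x) %*% sp@rotation, 2, sp@translation, "+")

#' Time-resolved RMSD against a reference frame
#'
#' Each frame's selected atoms are superposed (mass-weighted Kabsch) onto
#' the reference frame's, then the mass-weighted RMSD over the selection
#' is reported.  Units: Angstrom.  With \code{referenceFrame = 1} the
#' first value is 0.
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param referenceFrame index of the reference frame.
#' @param selection see \code{\link{selectAtoms}}; default backbone.
#' @param massWeighted weight atoms by mass (default TRUE).
#' @return a \linkS4class{LabeledSeries} (time in ps when known).
#' @export
rmsdSeries <- function(traj, referenceFrame = 1L, selection = "backbone",
                       massWeighted = TRUE) {
  idx <- selectAtoms(traj, selection)
  w <- if (massWeighted) atomInfo(traj)$mass[idx] else NULL
  ref <- traj@coords[referenceFrame, idx, , drop = TRUE]
  vals <- vapply(seq_len(nFrames(traj)), function(f)
    kabschSuperpose(traj@coords[f, idx, , drop = TRUE], ref, w)@postFitRMSD,
    numeric(1))
  t <- if (length(traj@times)) traj@times else seq_len(nFrames(traj)) - 1
  LabeledSeries(t, vals, title = "RMSD",
                xLabel = if (length(traj@times)) "Time (ps)" else "Frame",
                yLabel = "RMSD (Å)", legend = "RMSD")
}

# Superpose every frame onto a reference structure; returns the aligned
# coordinate array for the selection.
.alignFrames <- function(traj, idx, ref, w) {
  out <- array(NA_real_, c(nFrames(traj), length(idx), 3))
  for (f in seq_len(nFrames(traj))) {
    fr <- traj@coords[f, idx, , drop = TRUE]
    out[f, , ] <- applySuperposition(kabschSuperpose(fr, ref, w), fr)
  }
  out
}

#' Per-residue RMSF about the time-average structure
#'
#' Frames are superposed to the time-average structure (one refinement
#' pass: mean, superpose, re-mean), then
#' \eqn{RMSF_i = \sqrt{\langle |r_i - \langle r_i\rangle|^2 \rangle}} per
#' atom; the residue value is the mass-weighted mean over its selected
#' atoms.
#'
#' @inheritParams rmsdSeries
#' @return a \linkS4class{LabeledSeries} over residue numbers, with the
#'   per-atom RMSF attached as an extra column when selections differ.
#' @export
rmsfPerResidue <- function(traj, selection = "backbone",
                           massWeighted = TRUE) {
  idx <- selectAtoms(traj, selection)
  a <- atomInfo(traj)[idx, ]
  w <- if (massWeighted) a$mass else NULL
  m0 <- apply(traj@coords[, idx, , drop = FALSE], c(2, 3), mean)
  aligned <- .alignFrames(traj, idx, m0, w)
  m1 <- apply(aligned, c(2, 3), mean)
  dev2 <- sweep(aligned, c(2, 3), m1)^2
  atom_rmsf <- sqrt(rowSums(apply(dev2, c(2, 3), mean)))
  resid <- sort(unique(a$resid))
  vals <- vapply(resid, function(r) {
    sel <- a$resid == r
    sum(a$mass[sel] * atom_rmsf[sel]) / sum(a$mass[sel])
  }, numeric(1))
  LabeledSeries(resid, vals, title = "RMSF", xLabel = "Residue",
                yLabel = "RMSF (Å)", legend = "RMSF")
}

#' Radius of gyration series
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{com}|^2 / \sum_i m_i}} per frame,
#' in Angstrom.
#'
#' @inheritParams rmsdSeries
#' @export
radiusOfGyration <- function(traj, selection = "all") {
  idx <- selectAtoms(traj, selection)
  m <- atomInfo(traj)$mass[idx]
  vals <- vapply(seq_len(nFrames(traj)), function(f) {
    x <- traj@coords[f, idx, , drop = TRUE]
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }, numeric(1))
  t <- if (length(traj@times)) traj@times else seq_len(nFrames(traj)) - 1
  LabeledSeries(t, vals, title = "Radius of gyration",
                xLabel = if (length(traj@times)) "Time (ps)" else "Frame",
                yLabel = "Rg (Å)", legend = "Rg")
}

# Deterministic quasi-uniform sphere points (golden-spiral lattice).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Point sampling on each atom's solvent sphere (radius r_vdw + probe): a
#' point is exposed when inside no other atom's solvent sphere; the
#' atom's area is the exposed fraction of \eqn{4\pi (r_{vdw}+probe)^2}.
#' Units: Angstrom^2.  Radii come from a Bondi-style table; unknown
#' elements raise an error naming the atom type.
#'
#' @inheritParams rmsdSeries
#' @param probeRadius solvent probe radius, Angstrom (water: 1.4).
#' @param nSpherePoints quadrature points per atom (default 960).
#' @param radii optional named vector overriding the vdW table.
#' @return a \linkS4class{LabeledSeries} of total SASA per frame, with a
#'   \code{perAtom} attribute (frames x atoms matrix).
#' @export
sasaSeries <- function(traj, selection = "all", probeRadius = 1.4,
                       nSpherePoints = 960L, radii = NULL) {
  idx <- selectAtoms(traj, selection)
  a <- atomInfo(traj)[idx, ]
  tab <- .VDW_RADII
  if (!is.null(radii)) tab[names(radii)] <- radii
  key <- a$element; key[key == "NA"] <- "NA."
  rv <- tab[key]
  if (anyNA(rv))
    stop("no van der Waals radius for atom type(s): ",
         paste(unique(a$element[is.na(rv)]), collapse = ", "))
  R <- unname(rv) + probeRadius
  sph <- .spherePoints(nSpherePoints)
  nf <- nFrames(traj); na <- length(idx)
  per_atom <- matrix(NA_real_, nf, na)
  for (f in seq_len(nf)) {
    x <- traj@coords[f, idx, , drop = TRUE]
    x <- rbind(x)
    d2 <- as.matrix(stats::dist(x))^2
    for (i in seq_len(na)) {
      nbr <- which(d2[i, ] < (R[i] + R)^2 & seq_len(na) != i)
      pts <- sweep(sph * R[i], 2, x[i, ], "+")
      exposed <- rep(TRUE, nSpherePoints)
      for (j in nbr) {
        dj <- (pts[, 1] - x[j, 1])^2 + (pts[, 2] - x[j, 2])^2 +
              (pts[, 3] - x[j, 3])^2
        exposed <- exposed & dj >= R[j]^2
        if (!any(exposed)) break
      }
      per_atom[f, i] <- mean(exposed) * 4 * pi * R[i]^2
    }
  }
  t <- if (length(traj@times)) traj@times else seq_len(nf) - 1
  out <- LabeledSeries(t, rowSums(per_atom), title = "Solvent accessible surface",
                       xLabel = if (length(traj@times)) "Time (ps)" else "Frame",
                       yLabel = "Area (Å²)", legend = "Total SASA")
  attr(out, "perAtom") <- per_atom
  out
}

#' Hydrogen bond analysis
#'
#' Geometric criterion matching the GROMACS defaults: a donor-acceptor
#' pair is bonded in a frame when the donor-acceptor distance is at most
#' \code{distanceCutoff} \emph{and} the hydrogen-donor-acceptor angle is
#' at most \code{angleCutoff} degrees.  Donors are N/O atoms with a
#' covalently attached hydrogen (within \code{bondCutoff} in the first
#' frame); acceptors are all N/O atoms.
#'
#' @param traj a \linkS4class{Trajectory} containing hydrogens.
#' @param donorSelection,acceptorSelection selections restricting the
#'   donor heavy atoms and acceptors (default all N/O).
#' @param distanceCutoff donor-acceptor cutoff, Angstrom (default 3.5).
#' @param angleCutoff H-D-A cutoff, degrees (default 30).
#' @param bondCutoff covalent D-H assignment cutoff, Angstrom.
#' @return a list: \code{series} (count per frame,
#'   \linkS4class{LabeledSeries}), \code{records} (data.frame of donor,
#'   hydrogen, acceptor indices and occupancy), \code{presence} (pairs x
#'   frames logical matrix), \code{occupancy} (named occupancy fractions).
#' @export
hbondAnalysis <- function(traj, donorSelection = NULL,
                          acceptorSelection = NULL, distanceCutoff = 3.5,
                          angleCutoff = 30, bondCutoff = 1.25) {
  a <- atomInfo(traj)
  polar <- which(a$element %in% c("N", "O", "F"))
  don_heavy <- if (is.null(donorSelection)) polar
               else intersect(selectAtoms(traj, donorSelection), polar)
  acc <- if (is.null(acceptorSelection)) polar
         else intersect(selectAtoms(traj, acceptorSelection), polar)
  hyd <- which(a$element == "H")
  if (!length(hyd)) stop("no hydrogen atoms: cannot assign donors")
  x1 <- traj@coords[1, , , drop = TRUE]
  # covalent D-H pairs from the first frame
  pairs <- list()
  for (h in hyd) {
    dh <- sqrt(rowSums(sweep(rbind(x1[don_heavy, ]), 2, x1[h, ])^2))
    d <- don_heavy[dh <= bondCutoff]
    if (length(d)) pairs[[length(pairs) + 1L]] <- c(d[which.min(dh[dh <= bondCutoff])], h)
  }
  if (!length(pairs))
    stop("no donor-hydrogen pairs resolvable within ", bondCutoff, " A")
  dh <- do.call(rbind, pairs)
  # candidate triplets (donor, hydrogen, acceptor), acceptor != donor
  trip <- do.call(rbind, lapply(seq_len(nrow(dh)), function(k) {
    ac <- acc[acc != dh[k, 1]]
    if (!length(ac)) return(NULL)
    cbind(donor = dh[k, 1], hydrogen = dh[k, 2], acceptor = ac)
  }))
  nf <- nFrames(traj)
  cosCut <- cos(angleCutoff * pi / 180)
  presence <- matrix(FALSE, nrow(trip), nf)
  for (f in seq_len(nf)) {
    x <- traj@coords[f, , , drop = TRUE]
    D <- x[trip[, "donor"], , drop = FALSE]
    H <- x[trip[, "hydrogen"], , drop = FALSE]
    A <- x[trip[, "acceptor"], , drop = FALSE]
    da <- sqrt(rowSums((A - D)^2))
    v1 <- H - D; v2 <- A - D
    cosang <- rowSums(v1 * v2) /
      pmax(sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)), 1e-12)
    presence[, f] <- da <= distanceCutoff & cosang >= cosCut
  }
  seen <- rowSums(presence) > 0
  trip <- trip[seen, , drop = FALSE]
  presence <- presence[seen, , drop = FALSE]
  occ <- rowMeans(presence)
  lab <- if (nrow(trip)) {
    paste0(a$name[trip[, "donor"]], a$resid[trip[, "donor"]], "-",
           a$name[trip[, "acceptor"]], a$resid[trip[, "acceptor"]])
  } else character(0)
  t <- if (length(traj@times)) traj@times else seq_len(nf) - 1
  series <- LabeledSeries(t, colSums(presence), title = "Hydrogen bonds",
                          xLabel = if (length(traj@times)) "Time (ps)" else "Frame",
                          yLabel = "Number", legend = "Hbonds")
  records <- data.frame(donor = trip[, "donor"], hydrogen = trip[, "hydrogen"],
                        acceptor = trip[, "acceptor"], occupancy = occ,
                        pair = lab, stringsAsFactors = FALSE)
  list(series = series, records = records, presence = presence,
       occupancy = stats::setNames(occ, lab))
}
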