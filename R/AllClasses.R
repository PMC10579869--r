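#' @import methods
NULL

#' LabeledSeries: a labelled time/value scalar series
#'
#' The in-memory form of a GROMACS/Grace XVG payload: an ordered time axis,
#' a primary value column, optional extra columns, and the plot metadata
#' (title, axis labels, legends) the file carries.  Units travel with the
#' labels; no silent conversion is performed on read or write.
#'
#' @slot times numeric, non-decreasing; units as labelled (typically ps or ns).
#' @slot values numeric, same length as \code{times}.
#' @slot title,xLabel,yLabel single strings (may be empty).
#' @slot legend character; legend of the primary and any extra columns.
#' @slot extra list of numeric vectors, additional data columns beyond the
#'   second, each the same length as \code{times}.
#' @slot meta character; unrecognised \code{@} metadata lines preserved
#'   verbatim for lossless round-trips.
#' @export
setClass("LabeledSeries",
  representation(times = "numeric", values = "numeric",
                 title = "character", xLabel = "character",
                 yLabel = "character", legend = "character",
                 extra = "list", meta = "character"),
  prototype(title = "", xLabel = "", yLabel = "",
            legend = character(), extra = list(), meta = character()))

setValidity("LabeledSeries", function(object) {
  msg <- character()
  if (length(object@times) < 1L)
    msg <- c(msg, "series must contain at least one point")
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have identical length")
  if (is.unsorted(object@times, na.rm = TRUE))
    msg <- c(msg, "times must be non-decreasing")
  for (e in object@extra)
    if (length(e) != length(object@times))
      msg <- c(msg, "every extra column must match the series length")
  if (length(msg)) msg else TRUE
})

#' Trajectory: ordered frames of Cartesian coordinates
#'
#' Coordinates are stored in Angstrom (the PDB native unit) as an
#' \code{n_frames x n_atoms x 3} array, alongside per-atom metadata and
#' optional frame times in ps.  All frames share one atom order.
#'
#' @slot coords numeric array, frames x atoms x 3, Angstrom, finite.
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resid}, \code{resname}, \code{chain},
#'   \code{mass} (Da, all > 0).
#' @slot times numeric frame times in ps, or length 0 when unknown.
#' @export
setClass("Trajectory",
  representation(coords = "array", atoms = "data.frame", times = "numeric"),
  prototype(times = numeric()))

setValidity("Trajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be an n_frames x n_atoms x 3 array")
  else {
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (nrow(object@atoms) != d[2])
      msg <- c(msg, "atom table must have one row per atom")
    if (length(object@times) && length(object@times) != d[1])
      msg <- c(msg, "times must be empty or one per frame")
  }
  need <- c("serial", "name", "element", "resid", "resname", "chain", "mass")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atom table must carry columns:",
                        paste(need, collapse = ", ")))
  else if (any(!is.finite(object@atoms$mass) | object@atoms$mass <= 0))
    msg <- c(msg, "every atom must have mass > 0")
  if (length(msg)) msg else TRUE
})

#' CharMatrix: a residue-by-frame single-character code matrix
#'
#' The in-memory form of a GROMACS XPM matrix (secondary-structure
#' timelines, hydrogen-bond existence maps).  Row 1 is the matrix's bottom
#' y-axis row, matching the GROMACS axis convention.
#'
#' @slot codes character matrix (n_rows x n_cols), single-character cells.
#' @slot rowLabels,colLabels numeric axis tick values (may be empty).
#' @slot legend named character; maps each code to its class name.
#' @slot colors named character; maps each code to a colour string.
#' @slot title single string.
#' @export
setClass("CharMatrix",
  representation(codes = "matrix", rowLabels = "numeric",
                 colLabels = "numeric", legend = "character",
                 colors = "character", title = "character"),
  prototype(rowLabels = numeric(), colLabels = numeric(), title = ""))

setValidity("CharMatrix", function(object) {
  msg <- character()
  if (!is.character(object@codes))
    msg <- c(msg, "codes must be a character matrix")
  else {
    seen <- unique(as.vector(object@codes))
    bad <- setdiff(seen, names(object@legend))
    if (length(bad))
      msg <- c(msg, paste0("codes absent from the legend: ",
                           paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' PotentialSpec: an analytic or tabulated potential in kT units
#'
#' Ground-truth potentials for the synthetic Boltzmann and umbrella-window
#' generators.  Energies are expressed in kT; lengths in the (arbitrary)
#' reaction-coordinate unit, Angstrom by convention.
#'
#' @slot form one of \code{"harmonic"}, \code{"double_well"},
#'   \code{"tabulated"}, \code{"flat"}.
#' @slot params named list: \code{k} (kT/length^2) for harmonic;
#'   \code{barrier} (kT) and \code{separation} (length) for double_well;
#'   \code{x}, \code{u} vectors for tabulated.
#' @slot dimension 1 or 2.
#' @export
setClass("PotentialSpec",
  representation(form = "character", params = "list", dimension = "numeric"))

setValidity("PotentialSpec", function(object) {
  msg <- character()
  if (!object@form %in% c("harmonic", "double_well", "tabulated", "flat"))
    msg <- c(msg, "unknown potential form")
  if (!object@dimension %in% c(1, 2))
    msg <- c(msg, "dimension must be 1 or 2")
  if (object@form == "harmonic" &&
      (is.null(object@params$k) || object@params$k <= 0))
    msg <- c(msg, "harmonic spring constant must be > 0")
  if (object@form == "tabulated" &&
      (is.null(object@params$x) || is.null(object@params$u) ||
       any(!is.finite(object@params$u))))
    msg <- c(msg, "tabulated potential must be finite on its domain")
  if (length(msg)) msg else TRUE
})

#' Superposition: a proper rigid-body fit
#'
#' Result of a weighted Kabsch superposition: the rotation and translation
#' taking the mobile frame onto the reference (\code{x \%*\% rotation +
#' translation}), plus the RMSD after fitting.
#'
#' @slot rotation 3x3 orthonormal matrix, det = +1.
#' @slot translation length-3 numeric, Angstrom.
#' @slot postFitRMSD non-negative, Angstrom.
#' @export
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric",
                 postFitRMSD = "numeric"))

setValidity("Superposition", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6)
    msg <- c(msg, "rotation must be 3x3 orthonormal")
  else if (abs(det(R) - 1) > 1e-9)
    msg <- c(msg, "rotation must be proper (det = +1)")
  if (object@postFitRMSD < 0)
    msg <- c(msg, "postFitRMSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PCAResult: principal components of atomic coordinates
#'
#' @slot eigenvalues numeric, non-increasing, Angstrom^2.
#' @slot eigenvectors 3N x n_comp matrix, orthonormal columns.
#' @slot projections n_frames x n_comp score matrix.
#' @slot meanStructure n_atoms x 3 matrix, Angstrom.
#' @export
setClass("PCAResult",
  representation(eigenvalues = "numeric", eigenvectors = "matrix",
                 projections = "matrix", meanStructure = "matrix"))

setValidity("PCAResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (any(diff(ev) > 1e-9)) msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(ev < -1e-9)) msg <- c(msg, "eigenvalues must be >= 0 (numerically)")
  if (length(msg)) msg else TRUE
})

#' ClusterResult: GROMOS (Daura) conformational clusters
#'
#' @slot assignment integer, frame -> cluster id (1-based, size-ordered).
#' @slot centers integer, medoid frame index per cluster.
#' @slot sizes integer, non-increasing.
#' @slot cutoff RMSD cutoff, Angstrom.
#' @export
setClass("ClusterResult",
  representation(assignment = "integer", centers = "integer",
                 sizes = "integer", cutoff = "numeric"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (sum(object@sizes) != length(object@assignment))
    msg <- c(msg, "cluster sizes must sum to the number of frames")
  if (any(object@assignment[object@centers] != seq_along(object@centers)))
    msg <- c(msg, "every center must belong to its own cluster")
  if (length(msg)) msg else TRUE
})

#' FreeEnergySurface: Boltzmann-inverted 2D free energy landscape
#'
#' Relative free energies over a 2D histogram of two order parameters:
#' \eqn{\Delta G_{ij} = -kT \ln(P_{ij}/P_{max})}, with the most populated
#' bin at exactly 0 and empty bins carrying \code{Inf} (masked), never 0.
#'
#' @slot xEdges,yEdges bin boundaries in the order parameters' own units.
#' @slot counts integer matrix (nx x ny), non-negative.
#' @slot deltaG numeric matrix; \code{Inf} marks empty bins.
#' @slot temperature Kelvin.
#' @slot energyUnit "kT" or "kJ/mol".
#' @slot frameToBin n_frames x 2 integer matrix of (i, j) bin indices.
#' @slot minBin length-2 integer, indices of the most populated bin.
#' @slot xLabel,yLabel order-parameter labels.
#' @export
setClass("FreeEnergySurface",
  representation(xEdges = "numeric", yEdges = "numeric", counts = "matrix",
                 deltaG = "matrix", temperature = "numeric",
                 energyUnit = "character", frameToBin = "matrix",
                 minBin = "integer", xLabel = "character",
                 yLabel = "character"),
  prototype(xLabel = "", yLabel = ""))

setValidity("FreeEnergySurface", function(object) {
  msg <- character()
  dg <- object@deltaG; ct <- object@counts
  if (!all(dim(dg) == dim(ct)))
    msg <- c(msg, "deltaG and counts must share dimensions")
  if (any(ct < 0)) msg <- c(msg, "counts must be non-negative")
  fin <- is.finite(dg)
  if (any(fin & ct == 0) || any(!fin & ct > 0))
    msg <- c(msg, "empty bins must be Inf, occupied bins finite")
  if (any(dg[fin] < -1e-12)) msg <- c(msg, "finite deltaG must be >= 0")
  mb <- object@minBin
  if (length(mb) == 2L && dg[mb[1], mb[2]] != 0)
    msg <- c(msg, "deltaG at minBin must be exactly 0")
  if (sum(ct) != sum(stats::complete.cases(object@frameToBin)))
    msg <- c(msg, "counts must sum to the number of binned frames")
  if (length(msg)) msg else TRUE
})

#' DensityEstimate: a 1D Gaussian kernel density estimate
#'
#' Holds the evaluation grid, the estimated density, the bandwidth, the
#' companion histogram, and the names of the rules that chose them.
#'
#' @slot grid,density numeric, equal length; density >= 0.
#' @slot bandwidth positive smoothing bandwidth h.
#' @slot n sample count.
#' @slot histEdges,histCounts companion histogram.
#' @slot kernel,binRule,bwRule rule names.
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", density = "numeric",
                 bandwidth = "numeric", n = "integer",
                 histEdges = "numeric", histCounts = "integer",
                 kernel = "character", binRule = "character",
                 bwRule = "character"),
  prototype(kernel = "gaussian"))

setValidity("DensityEstimate", function(object) {
  msg <- character()
  if (length(object@grid) != length(object@density))
    msg <- c(msg, "grid and density must have equal length")
  if (any(object@density < 0)) msg <- c(msg, "density must be >= 0")
  if (object@bandwidth <= 0) msg <- c(msg, "bandwidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' UmbrellaWindowSet: harmonically restrained reaction-coordinate samples
#'
#' One entry per umbrella window: restraint center, spring constant (kT per
#' length^2) and the reaction-coordinate samples collected under the bias.
#'
#' @slot centers numeric restraint centers, consistent length unit.
#' @slot springK numeric spring constants, kT/length^2, >= 0 (0 encodes
#'   an unbiased window, the direct-inversion limit).
#' @slot samples list of numeric vectors, one per window, each non-empty.
#' @export
setClass("UmbrellaWindowSet",
  representation(centers = "numeric", springK = "numeric", samples = "list"))

setValidity("UmbrellaWindowSet", function(object) {
  msg <- character()
  nw <- length(object@centers)
  if (length(object@springK) != nw || length(object@samples) != nw)
    msg <- c(msg, "centers, springK and samples must align")
  if (any(object@springK < 0)) msg <- c(msg, "spring constants must be >= 0")
  if (any(!vapply(object@samples, length, 1L)))
    msg <- c(msg, "every window must have at least one sample")
  if (length(msg)) msg else TRUE
})

#' PMFProfile: WHAM potential of mean force
#'
#' @slot binCenters reaction-coordinate bin centers.
#' @slot pmf free energy per bin (min over covered bins = 0); \code{Inf}
#'   marks uncovered bins.
#' @slot windowF converged per-window free-energy constants F_i (F_1 = 0).
#' @slot iterations iterations used.
#' @slot residual final max |dF_i|.
#' @slot residualHistory residual after each sweep.
#' @slot energyUnit "kT" or "kJ/mol".
#' @slot deltaGBind binding free energy, length 0 until computed.
#' @export
setClass("PMFProfile",
  representation(binCenters = "numeric", pmf = "numeric",
                 windowF = "numeric", iterations = "integer",
                 residual = "numeric", residualHistory = "numeric",
                 energyUnit = "character", deltaGBind = "numeric"),
  prototype(energyUnit = "kT", deltaGBind = numeric()))

setValidity("PMFProfile", function(object) {
  msg <- character()
  cov <- is.finite(object@pmf)
  if (any(cov) && abs(min(object@pmf[cov])) > 1e-9)
    msg <- c(msg, "minimum PMF over covered bins must be 0")
  if (any(!is.finite(object@windowF)))
    msg <- c(msg, "window constants must be finite")
  if (length(msg)) msg else TRUE
})

#' PullTrace: joined steered-MD force and displacement traces
#'
#' @slot times ps, strictly increasing.
#' @slot force kJ/mol/nm.
#' @slot displacement nm, relative to the first joined point.
#' @slot peakForce,peakTime the maximum force and when it occurs.
#' @export
setClass("PullTrace",
  representation(times = "numeric", force = "numeric",
                 displacement = "numeric", peakForce = "numeric",
                 peakTime = "numeric"))

setValidity("PullTrace", function(object) {
  msg <- character()
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@force) != length(object@times) ||
      length(object@displacement) != length(object@times))
    msg <- c(msg, "force and displacement must align with times")
  if (length(msg)) msg else TRUE
})
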