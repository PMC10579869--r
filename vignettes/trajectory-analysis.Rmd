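---
title: "Trajectory analysis, free energy landscapes and WHAM with TrajKit"
author: "TrajKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory analysis, free energy landscapes and WHAM with TrajKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrajKit)
```

TrajKit analyses molecular dynamics output after the simulation is
over. This vignette is the package's account of the models it
implements, the parameters that matter, the numerical conventions it
commits to, and what its synthetic ground-truth generators do and do
not emulate.

## Containers and units

Trajectories are `frames × atoms × 3` coordinate arrays in Ångström
(the PDB native unit) with per-atom metadata and masses; scalar
observables travel as `LabeledSeries` (the in-memory form of a
Grace/GROMACS XVG file) and keep whatever units their labels declare —
the package never rescales a series silently, because GROMACS tools
write nm while PDB files are in Å and a silent conversion is exactly
where factor-of-10 errors enter. Secondary-structure timelines are
character matrices whose row 1 is the *bottom* y-axis row, matching the
GROMACS XPM convention (the file stores the top pixel row first).

## Structural metrics

**Superposition.** All deviation metrics superpose frames with the
Kabsch SVD algorithm, weighted by atomic mass by default, with the
reflection branch corrected so only proper rotations are returned.
Configurations of rank < 2 (collinear atoms) are rejected rather than
silently fit.

**RMSD / RMSF.** RMSD is computed per frame against a reference frame
(frame 1 by default) over a selection (backbone by default; Rg and SASA
default to all atoms — the conventional choices, both overridable).
RMSF uses the time-average structure as reference, with one refinement
pass: average, superpose all frames to that average, re-average. The
per-residue value is the mass-weighted mean over the residue's selected
atoms. Note a finite-size caveat: superposition removes six rigid
degrees of freedom, so for N atoms with isotropic per-coordinate
fluctuation σ the observed RMSF is σ√3·√(1 − 6/(3N)), about 2% below
σ√3 at N = 60. Tests and the acceptance script use N = 60, 2000 frames
— large enough that the closed form holds to within the 5% sampling
band, small enough that the whole suite runs in seconds.

**SASA.** Shrake–Rupley point sampling: 960 quasi-uniform
(golden-spiral) points per atom on the solvent sphere r_vdw + probe
(probe 1.4 Å), Bondi-style van der Waals radii, error raised for
unknown elements. 960 points put the quadrature error for an isolated
atom well under 1%; because the point set is fixed in the laboratory
frame, SASA is rotation-invariant only to the quadrature resolution
(~1% at 960 points), which is how the invariance test is toleranced.
The double-cubic-lattice acceleration computes the same quantity and is
deliberately not used: the direct sum keeps the contract simple at the
problem sizes this package targets.

**Hydrogen bonds.** The geometric criterion matches the GROMACS
defaults: donor–acceptor distance ≤ 3.5 Å *and* hydrogen–donor–acceptor
angle ≤ 30°, both exposed as arguments. Donors are N/O atoms with a
hydrogen within 1.25 Å in the first frame; acceptors are all N/O.
Per-pair presence flags across frames give the occupancy matrix.

## PCA and clustering

PCA superposes frames to the mean structure, then diagonalises the
covariance of the 3N coordinate vectors. The sample covariance uses the
n−1 denominator, so projection covariances equal the eigenvalues
exactly. Coordinates are unweighted by default (`massWeighted = TRUE`
reproduces the mass-weighted convention some workflows use).

Clustering is the GROMOS/Daura greedy algorithm on the pairwise
post-fit RMSD matrix: the frame with the most neighbours within the
cutoff seeds a cluster, the cluster is removed, repeat. Ties break to
the lowest frame index and clusters are numbered by decreasing size
then center index, making the result deterministic given the distance
matrix. The O(n²) matrix is computed once; this bounds practical use to
a few thousand frames, which is the regime conformational clustering is
used in.

## Free energy landscapes

`buildFEL` bins two frame-aligned order parameters on an equal-width 2D
grid spanning their observed ranges and applies Boltzmann inversion,
ΔG = −kT ln(P/P_max). Conventions the package commits to:

* the most probable bin is *exactly* 0 (assigned, not just computed,
  to avoid floating-point noise at the anchor);
* empty bins are masked as `Inf`, never given pseudo-counts — the
  inversion is undefined at P = 0 and pseudo-counts distort basin
  depths;
* energies are in kT by default, or kJ/mol via
  k_B = 0.0083144626 kJ·mol⁻¹·K⁻¹ and the stated temperature;
* the frame→bin map is stored, so `extractMinEnergyFrames` can pull
  the members of the zero bin (or any user-chosen bin) back out of the
  trajectory in frame order.

The natural order-parameter pairs are (PC1, PC2) from `trajectoryPCA`
and (RMSD, Rg); any two aligned series are accepted.

## Kernel density estimation

`kdeEstimate` implements the Gaussian-kernel estimator on an even grid
spanning the data range ± 4h. Bandwidth rules: Silverman
(0.9·min(σ̂, IQR/1.34)·n^(−1/5), default) and Scott; explicit h always
wins. Histogram bin rules for the companion histogram:
Freedman–Diaconis (default), Sturges, Scott, square-root. A
zero-variance sample with an automatic rule is an error that points the
user to explicit h. Comparative KDE evaluates every dataset on one
shared grid (union range padded by 4·max h) with per-dataset
normalisation.

## Secondary structure

`reclassifySS` reduces the 7-type DSSP timeline alphabet to the four
basic classes: {H, G, I} → Helix, {E, B} → Sheet, {T} → Turn, and
{S, C, "~"} → Coil. Grouping the bend code S with Coil (rather than
Turn) is the documented default — bends are geometric, not
hydrogen-bonded, features — and `bendTo = "turn"` selects the
alternative. Unknown codes fail loudly with their cell location.
Fraction series per class sum to 1 in every frame, and reclassification
commutes with fraction computation (summing member-class fractions),
which the suite checks on random matrices.

## Replica averaging

`averageSeries` aligns replicas by linear interpolation onto the first
replica's time grid, within each replica's own range only (no
extrapolation), and reports per-point mean and sample (n−1) SD over the
covering replicas, flagging points covered by fewer than two. The first
grid is the natural reference since replicas of one protocol share a
nominal schedule; disjoint ranges are an error, not an empty average.

## Steered MD and umbrella sampling

`pullAnalysis` joins force and COM-position traces on common times
(exact, or nearest within half the median sampling interval), reports
displacement relative to the first joined point, and the peak force and
its time — the three standard views of a pulling run.

`selectWindows` chooses umbrella starting frames by a greedy walk:
start at frame 1, then repeatedly take the frame whose distance is
nearest to (last distance + spacing), ties to the earlier frame,
stopping once the target passes the final frame's distance. A spacing
wider than the whole range degenerates to {first, last} with a warning.

`wham` iterates the standard self-consistent equations on a shared
histogram (equal-width bins over the union of window sample ranges, 200
by default). Numerical conventions: the gauge is fixed by F₁ = 0;
convergence is max |ΔF_i| < 1e-6 kT (overridable) with a 100,000
iteration cap, and non-convergence is an error carrying the residual,
not a silent result; the residual history is retained so solver
behaviour is inspectable; zero-count bins are masked; adjacent windows
with no shared occupied bin trigger a warning naming the gap. Energies
are kT throughout, with kJ/mol an output-scaling option. A zero spring
constant is legal in the container and reduces WHAM to direct histogram
inversion — the one-window sanity limit.

`bindingEnergy` averages the PMF over the terminal fraction of covered
bins (10% by default) and reports that unbinding cost and its negative
as ΔG_bind. A plateau average is used rather than the single endpoint
bin because the endpoint is the worst-sampled bin of the profile; the
fraction is a parameter, and this convention is the package's own.

## The synthetic generators, and what passing tests mean

The generators produce every input class from stated distributions:

* `makeFluctuatingTrajectory` — a kinked reference chain (3.8 Å
  pseudo-Cα spacing) plus i.i.d. isotropic Gaussian displacements of
  stated amplitude, optionally wrapped in per-frame random rigid
  motions to exercise superposition. Closed forms: RMSF → amplitude·√3,
  post-fit RMSD of the rigid-motion-only case → 0.
* `sampleBoltzmann` — Metropolis Monte Carlo from exp(−U/kT) with a
  Gaussian proposal. The documented constants are burn-in 1,000 steps,
  thinning 10, and a proposal width of ~2.4× the target scale (giving
  ~40–50% acceptance on near-Gaussian targets); all are arguments. The
  stream is fixed entirely by the seed.
* `makeUmbrellaWindows` — per-window Metropolis sampling of
  U + ½k(ξ−c_i)², window i seeded at seed + i − 1, started at its own
  center.
* `makeSSMatrix` — i.i.d. draws from a code alphabet with stated
  weights, with every code guaranteed to appear once the matrix has at
  least as many cells as codes.

Study conditions used by the tests and the acceptance script, chosen
once: FEL recovery uses 50,000 samples from the 2D unit harmonic well
on a 24×24 grid, compared to the analytic Gaussian bin masses over bins
with ≥ 50 counts (0.15 kT RMS band); WHAM recovery uses 10 windows at
centers −2.5…2.5, spring 20 kT/unit², 5,000 samples per window, 100
bins, compared to ½x² over bins with ≥ 100 total counts (0.2 kT RMS
band). These sizes keep the full suite under half a minute on one CPU
while leaving the statistical bands comfortably wide.

What the generators do *not* emulate: force-field physics, solvent,
correlated collective motions (displacements are independent per atom
and per frame), realistic secondary-structure autocorrelation, or
pulling hysteresis. Passing tests therefore demonstrate that the
estimators recover known ground truth under their stated assumptions —
not that any particular biological system is well sampled. On real
trajectories, sampling quality, not estimator correctness, is the
dominant error source.

## Degenerate inputs and tie-breaks, in one place

* Superposition: < 3 atoms or rank < 2 → error; reflection corrected.
* FEL: all samples in one bin → a valid surface with a single 0 bin;
  ties for the most populated bin break to the first in column-major
  order.
* Clustering: neighbour-count ties break to the lowest frame index.
* Window selection: nearest-distance ties break to the earlier frame.
* KDE: zero variance → error advising explicit h.
* WHAM: empty histogram support → error; window-gap → warning.
* Binding energy: a PMF whose minimum is its last covered bin has no
  plateau beyond it → error.

## Known limitations

Pairwise-RMSD clustering is O(n²) in frames; SASA is O(atoms ×
neighbours × points) per frame; the WHAM solver is the direct
self-consistent iteration (no MBAR, no bootstrap error bars); XPM
support is the 1-character-per-pixel GROMACS dialect; trajectory input
is text PDB (binary XTC/TRR is out of scope by design — export to
multi-model PDB upstream).
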