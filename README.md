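# TrajKit

TrajKit is an R package for the post-simulation half of a molecular
dynamics study: given a trajectory and the scalar observables derived
from it, it computes the structural metrics, conformational summaries
and free-energy estimates that MD practitioners routinely produce with
the GROMACS analysis modules — natively, with no GROMACS installation,
on portable text formats (multi-model PDB trajectories, Grace/GROMACS
XVG series, GROMACS XPM matrices, CSV).

It is aimed at structural bioinformaticians who have trajectories (or
exported observable series) in hand and want a scriptable, testable
analysis stack: per-frame RMSD/RMSF/Rg/SASA and hydrogen bonds,
principal component analysis, GROMOS conformational clustering,
free energy landscapes, kernel density estimates, secondary-structure
timeline simplification, replica averaging, and steered-MD/umbrella
sampling analysis with a native WHAM solver.

## The statistics at the core

**Free energy landscape by Boltzmann inversion.** Two per-frame order
parameters (for example PC1/PC2, or RMSD/Rg) are binned on a 2D
histogram, and bin populations become relative free energies:

    ΔG_i = −kT ln( P_i(r) / P_max(r) )

The most probable state sits at exactly 0; empty bins are masked rather
than given pseudo-counts, because the inversion is undefined at zero
population. The frame→bin map is retained so the lowest-energy
structures can be extracted back out of the trajectory.

**Kernel density estimation.** Observable distributions are estimated
with the Gaussian-kernel estimator

    f̂_h(x) = 1/(nh) Σ_i K((x − x_i)/h)

with Silverman/Scott bandwidth rules and Freedman–Diaconis, Sturges,
Scott or square-root histogram bin rules (all overridable).

**WHAM.** Umbrella-sampling windows (harmonic restraints ½k(ξ−c_i)² at
staggered centers) are de-biased by self-consistent iteration of

    P(ξ_b) = Σ_i n_ib / Σ_i N_i exp((F_i − w_i(ξ_b))/kT)
    F_i    = −kT ln Σ_b P(ξ_b) exp(−w_i(ξ_b)/kT)

until the window constants stabilise; the PMF is −kT ln P shifted to a
zero minimum, and the binding free energy is read off the terminal
plateau of the PMF.

Every generator of synthetic input (fluctuating trajectories, Metropolis
Boltzmann samplers, umbrella windows, secondary-structure matrices) is a
first-class, seeded part of the package, so the whole stack is testable
against known ground truth without downloading anything.

## Worked example

```r
library(TrajKit)

# a 60-residue chain fluctuating with 0.5 A per-coordinate amplitude
traj <- makeFluctuatingTrajectory(nAtoms = 60, nFrames = 2000,
                                  amplitude = 0.5, seed = 7)
rmsf <- rmsfPerResidue(traj, selection = "all")
mean(seriesValues(rmsf))
#> [1] 0.8520952

# isotropic Gaussian displacements have RMSF = amplitude * sqrt(3):
0.5 * sqrt(3)
#> [1] 0.8660254

# umbrella sampling on a harmonic well, de-biased by WHAM
ws <- makeUmbrellaWindows(harmonicPotential(k = 1),
                          centers = seq(-2.5, 2.5, length.out = 10),
                          springK = 20, nPerWindow = 5000, seed = 4)
pmf <- wham(ws, nBins = 100)
pmf
#> PMFProfile: 100 bins (100 covered), 274 iteration(s), residual 9.9e-07 kT
```

The recovered PMF tracks the generating potential ½x² to well under
0.1 kT RMS over the well-populated bins — the de-biasing, not the
restraints, shapes the curve.

A command-line front end (`inst/cli/trajkit.R`) exposes each analysis as
a subcommand (`rmsd`, `rg`, `fel`, `wham`, ...) writing XVG/CSV outputs
plus a JSON run manifest:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/trajkit.R", package="TrajKit"))')" \
    rg --traj traj.pdb --out rg.xvg
```

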