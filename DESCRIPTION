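Package: TrajKit
Title: Native Analysis of Molecular Dynamics Trajectories, Free Energy
    Landscapes and Umbrella Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-simulation analysis of molecular dynamics trajectories
    without a GROMACS installation: structural metrics (Kabsch
    superposition, RMSD, RMSF, radius of gyration, Shrake-Rupley solvent
    accessible surface area, hydrogen bonds), principal component
    analysis and GROMOS (Daura) conformational clustering, free energy
    landscapes by Boltzmann inversion with lowest-energy frame
    extraction, kernel density estimation of trajectory observables,
    DSSP secondary-structure timeline simplification, replica-averaged
    series, and steered-MD/umbrella-sampling analysis with a native
    weighted histogram analysis method (WHAM) solver for the potential
    of mean force and binding free energy. Reads and writes the GROMACS
    text dialects (XVG series, XPM character matrices) and multi-model
    PDB trajectories, and ships seeded synthetic generators for every
    input class.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), bio3d, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
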