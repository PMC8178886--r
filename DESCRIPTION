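Package: enzstab
Title: Enzyme Storage-Stability Study Design, Deactivation Kinetics and
    Trajectory Fluctuation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistically designed enzyme storage-stability studies and
    their downstream analysis. Provides pilot-variance pooling and
    stratified sampling design with proportional allocation and
    finite-population correction; volumetric, relative and specific
    activity calculations for chromogenic oxidase assays; first-order
    thermal deactivation fits per storage isotherm with Arrhenius
    accelerated-stability inference and transition-state thermodynamic
    parameters (half-life, enthalpy, Gibbs energy, entropy of
    inactivation); Michaelis-Menten parameter estimation by Hanes-Woolf
    linearization and nonlinear least squares; and molecular-dynamics
    trajectory post-processing (Kabsch superposition, RMSD, per-residue
    backbone RMSF, temperature-difference RMSF with cutoff flagging,
    fluctuating-region detection, and C-alpha covariance principal
    component analysis). A synthetic-data generator with known ground
    truth supports parameter-recovery validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
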