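Package: geomroute
Title: Geometric Route to Standard Binding Free Energies from Restrained
    Potential-of-Mean-Force Calculations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for computing standard (absolute) host-guest binding
    free energies by the geometric route: collective variables with analytic
    gradients (separation distance, polar and Euler angles from optimal
    superposition, conformational RMSD, dihedrals), an extended adaptive
    biasing force (eABF) sampler with window stratification and the CZAR
    estimator, restraint free-energy extraction from potentials of mean
    force, the standard-state correction, and thermodynamic-cycle
    composition into an equilibrium constant and binding free energy.
    Includes analytic toy host-guest systems with a Langevin-dynamics
    sampler, a brute-force configurational-integral oracle for validation,
    and dihedral-based conformer classification of ligand time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
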