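Package: pfv
Title: Protein Film Voltammetry: Simulation, Thermodynamics and
    Electron-Transfer Kinetics of Surface-Confined Redox Couples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the analysis chain of protein film voltammetry on
    self-assembled monolayer (SAM) electrodes: simulation of
    quasi-reversible one-electron surface-confined cyclic voltammograms
    under Butler-Volmer (Laviron) kinetics with a stiffness-proof
    exponential integrator; baseline correction, peak picking, midpoint
    potentials, exchanged charge and surface coverage; reduction
    thermodynamics from temperature-dependent midpoint potentials in a
    non-isothermal cell (reaction entropy from dE/dT, enthalpy via
    Gibbs-Helmholtz) with enthalpy/entropy compensation diagnostics;
    fitting of a three-acid-base-equilibria model for the pH dependence
    of the formal potential with multi-start bounded nonlinear least
    squares; and heterogeneous electron-transfer kinetics (Laviron
    trumpet-plot rate constants, Arrhenius activation enthalpy, Marcus
    reorganization energy, and electron-tunneling distance intervals).
    All pipeline inputs can be generated synthetically with known ground
    truth, so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
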