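Package: plasmaMD
Title: Hybrid Plasma/Molecular-Dynamics Simulation of XFEL-Induced Local
    Radiation Damage in Protein Nanocrystals
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the femtosecond ionization and ion dynamics driven by
    intense X-ray free-electron laser (XFEL) pulses in protein nanocrystals,
    with a focus on disulfide-bridge Coulomb explosion and its suppression by
    plasma-electron screening and ion caging. Implements per-element ionization
    rate equations (photoionization, Auger decay, electron-impact ionization),
    a continuum trapped-electron plasma model supplying a time-dependent Debye
    screening parameter, Runge-Kutta ion dynamics under screened pairwise
    potentials in a periodic supercell, an X-ray pump/X-ray probe experiment
    driver with jackknife ensemble statistics, and a Bragg-termination
    diffraction-intensity simulator with Wilson-plot and cumulative-intensity
    diagnostics. Synthetic-data generators (solvated-protein supercell, vacuum
    disulfide, Wilson-distributed reference intensities) make the full pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
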