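Package: trackchem
Title: Track-Structure and Water-Radiolysis Monte Carlo Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Event-by-event simulation of charged-particle track structure in
    liquid water and of the radiation chemistry it initiates. A discrete
    (step-by-step) physics stage transports electrons, protons, hydrogen and
    helium atoms with tabulated cross sections and emits energy deposits and
    activated water molecules; a physicochemical stage dissociates activated
    water into radicals and ions; a step-by-step diffusion-reaction chemical
    stage evolves the molecular population from 1 ps to 1 us using
    Smoluchowski reaction radii, a dynamic time step, Gaussian diffusion and a
    Brownian-bridge encounter check. Observables include G-value time
    profiles, LET, radial dose distributions and LET scans. A calibratable
    synthetic track generator reproduces configured 1 ps yields so the
    chemical stage can be exercised without high-fidelity cross-section data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
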