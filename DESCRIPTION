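Package: bystandr
Title: Cellular-Automaton Simulation of Radiation-Induced Bystander Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A stochastic cellular-automaton model of radiation-induced
    bystander effects in two-dimensional cell cultures. Radiation is
    delivered as Poisson-distributed track traversals; irradiated cells
    release two virtual intercellular signals, one diffusing through the
    culture medium and one restricted to gap-junction-coupled cell
    networks, modelled by an explicit lattice diffusion scheme with
    pathway-specific direction constants. Both signals, direct dose and
    endogenous background induce DNA double-strand breaks (DSBs) as
    Poisson counts; DSBs are repaired by per-break Bernoulli thinning and
    drive a per-cell virtual clock with checkpoint arrest, reproductive
    and interphase death, division and quiescence. Includes scenario
    builders for multi-colony irradiation experiments, forward harnesses
    for DSB-decay, DSB-positive-fraction and clonogenic-survival
    calibration, and a grid-search fitter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
LinkingTo:
    Rcpp
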