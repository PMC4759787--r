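Package: dsbkin
Title: Stochastic Kinetics of DNA Double-Strand-Break Repair and gamma-H2AX Foci
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Single-site stochastic model of DNA double-strand-break (DSB)
    repair in which a telegraph damage signal is coupled to recruitment of
    activated repair factors (pATM) and phosphorylation of the histone H2AX
    (gamma-H2AX). Provides an exact Gillespie simulator of the jump process,
    moment-closure reductions to ordinary differential equations (an
    independence closure and a conditional-mean closure), least-squares
    parameter estimation from per-cell DSB and gamma-H2AX focus counts by
    Nelder-Mead search, and two model extensions: reversible sequestration of
    gamma-H2AX by a cell-penetrating anti-gamma-H2AX-TAT antibody, and de novo
    DSB induction by Auger electrons when the antibody carries In-111. A
    synthetic-data generator emulating the irradiation time-course design, a
    detectable-foci thresholding analysis and a command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    jsonlite,
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
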