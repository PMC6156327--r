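Package: emtdyn
Title: Dynamics of the miR-200/ZEB Epithelial-Mesenchymal Switch
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic, stochastic and delayed dynamics of a minimal
    two-variable gene-regulatory model of the microRNA-200/ZEB mutual
    inhibition circuit that governs epithelial-mesenchymal transitions of
    cancer cells. Provides exact fixed-point analysis via a scalar reduction,
    phenotype labelling (epithelial, mesenchymal, hybrid), phase diagrams in
    the (a, b) signal plane, bifurcation scans along SNAIL-signal pathways,
    Euler-Maruyama Langevin simulation, stationary distributions by Monte
    Carlo and by a finite-volume steady-state Fokker-Planck solve, potential
    landscapes with minimax-saddle barrier heights, mean first-passage times,
    and delay-differential simulation of delayed ZEB self-activation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
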