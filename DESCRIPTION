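Package: clockdde
Title: Delay Differential Equation Modeling of Core-Clock and
    Clock-Controlled Gene Expression Across Tissues
Version: 0.1.0
Authors@R:
    person("clockdde", "maintainers", email = "clockdde@example.org",
           role = c("aut", "cre"))
Description: Tools for modeling circadian gene expression with constant-delay
    delay differential equations (DDEs). Implements a method-of-steps
    integrator with dense output, the five-gene core-clock network
    (Bmal1, Rev-Erba, Per2, Cry1, Dbp) with interlocked Ebox/RRE/Dbox
    feedback, a one-way-coupled clock-controlled gene (CCG) model whose
    Ebox/RRE/Dbox exponents are derived from position-weight-matrix promoter
    scans, bounded nonlinear least-squares parameter estimation with Wald
    confidence intervals, local sensitivity analysis of oscillator phases,
    regulation-factor variability statistics, and seeded synthetic-data
    generators emulating a multi-tissue circadian microarray design.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
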