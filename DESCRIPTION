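Package: rab5onset
Title: Kinetic Modeling of Delayed-Onset Rab5 Activation by Rabex-5 and
    Rabaptin-5
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-variable kinetic model of Rab5 GTPase activation by the
    guanine nucleotide exchange factor Rabex-5 through a direct
    membrane-targeting pathway and an indirect Rabaptin-5-mediated positive
    feedback loop. Provides ODE simulation, closed-form steady-state response
    curves, the delayed-onset threshold, generalized Hill-coefficient
    sensitivity analysis, steady-state stability and transcritical bifurcation
    analysis, densitometry standard-curve protein quantification with
    per-cell mass to molarity conversion, a seeded generator of synthetic
    Tet-Off induction time courses, and an onset-detection pipeline that
    estimates the affinity (lambda/gamma) of the
    Rabex-5/Rabaptin-5/Rab5-GTP tripartite complex.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
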