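Package: tgicomb
Title: Tumor Growth Inhibition Modelling for Two-Drug Combination Xenograft
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacokinetic-pharmacodynamic modelling of tumor growth in
    xenograft mice treated with two anticancer agents given in combination.
    Extends the four-state Simeoni tumor growth inhibition model to a
    sixteen-state damage matrix in which a single interaction parameter
    (gamma) multiplies the product of the two plasma concentrations acting
    on the proliferating cells.  Provides closed-form linear compartmental
    pharmacokinetics under multi-dose regimens, stiff ODE simulation of
    control, monotherapy, combination, zero-interaction and cross-potency
    model variants, staged nonlinear weighted least-squares estimation of
    the pharmacodynamic parameters and of gamma, time-efficacy and
    synergistic/antagonistic combination indexes, prediction of new
    dose/schedule arms, and a synthetic-data generator for group-mean
    xenograft experiments with proportional noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
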