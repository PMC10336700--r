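Package: unli2d
Title: Two-Dimensional Unit Normal Loss Integral and Value-of-Information
    Analysis for Three-Strategy Decision Problems
Version: 1.0.0
Authors@R:
    person("VoI", "Developer", email = "voi.developer@example.com",
           role = c("aut", "cre"))
Description: Closed-form evaluation of the unit normal loss integral (UNLI)
    in one and two dimensions, i.e. E(max(Y, 0)) for (bivariate) normal Y,
    and a toolkit built around it for value-of-information analysis of
    decision problems with three strategies. Computes the expected value of
    perfect information (EVPI) either directly from bivariate-normal
    parameters of the incremental net benefits or from patient-level data
    of a parallel three-arm trial (closed-form and stratified-bootstrap
    estimators, Rubin pooling of multiply-imputed estimates,
    willingness-to-pay sweeps). Includes a seeded Monte-Carlo oracle, a
    252-setting factorial verification study of the closed form, a
    synthetic three-arm trial generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
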