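Package: ageadapt
Title: Model-Based Analysis of Facial Age Adaptation Aftereffects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing norm-based (renormalization) and
    multichannel (local repulsion) accounts of facial age adaptation
    aftereffects. Provides the Gaussian-derivative repulsion and
    one-parameter renormalization prediction functions, constrained and
    unconstrained least-squares fitting with multi-start optimisation,
    model comparison by RMS error with a Wilcoxon signed-rank test on
    paired absolute residuals, the intercept-curve regression simulation
    that discriminates the two accounts, and a synthetic pre/post
    perceived-age rating generator for power and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
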