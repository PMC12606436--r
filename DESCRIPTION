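Package: twosexsel
Title: Two-Sex Polygenic Adaptation Under Sex-Specific Stabilizing Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher allele-frequency simulation and analytic
    theory for a highly polygenic quantitative trait expressed in both sexes
    and subject to sex-specific Gaussian stabilizing selection, mutation, and
    genetic drift. Provides the mutation model over allelic magnitudes and
    sex-bias angles, calibration of the mutational input to a target
    equilibrium variance via the Dawson-function sojourn integral, equilibrium
    predictions for sex-specific variances, the intersex covariance and
    correlation, drift-induced sexual dimorphism, two-sex breeder's-equation
    dynamics after shifts in sex-specific optima, equilibration timescales for
    the fixed genetic backgrounds, and a config-driven scenario runner with
    replicate aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    deSolve,
    withr,
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
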