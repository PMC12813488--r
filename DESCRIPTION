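Package: connsig
Title: Connectome Predictive Neurosignatures of Reduced Sleep
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and transporting brain-wide functional
    connectivity neurosignatures of reduced sleep duration. Implements
    connectome construction from parcellated BOLD time series (motion
    censoring, nuisance regression, Fisher r-to-z, run averaging), a
    just-identified three-indicator latent sleep-duration factor,
    principal-component regression predictive modeling with one-standard-error
    component selection and leave-one-site-out cross-validation, Haufe
    activation-pattern transforms, Freedman-Lane permutation inference with
    nested exchangeability blocks (site/family/twin), dot-product expression
    scoring for longitudinal and sleep-deprivation cohorts, and a
    dual-permutation test of spatial correspondence between independently
    derived signatures. A synthetic-cohort generator reproduces the
    statistical structure of multisite developmental imaging samples so the
    full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    sandwich,
    lmtest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
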