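Package: pacflux
Title: Repeatability and Precision of Sheep Gas Measurements in Portable
    Accumulation Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for gaseous emission (CH4, CO2) and consumption
    (O2) measurements of sheep in portable accumulation chambers (PAC).
    Converts three-point chamber concentration traces to volumetric fluxes
    (l/h) and daily mass output (g/d), estimates between-animal, between-day
    and residual variance components of the fluxes with a crossed
    random-effects model (balanced-ANOVA closed form and REML), derives the
    animal variance share, coefficient of variation and repeatability,
    computes number-of-days precision curves, quantifies inter-day ranking
    consistency, and evaluates a mixed-model prediction equation by
    stratified cross-validation. Includes a synthetic trial generator with
    the additive animal + day + error variance structure so every stage is
    testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
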