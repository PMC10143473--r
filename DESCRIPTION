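Package: crsoil
Title: Soil Chromium Pollution, Ecological and Health Risk Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assessment toolkit for total chromium in industrial soils.
    Computes the geoaccumulation index (Igeo, Muller index) and the
    Hakanson monomial potential ecological risk index (E) with their
    standard class schemes, non-carcinogenic health-risk hazard quotients
    for children and adults via the USEPA three-pathway soil exposure
    model (ingestion, dermal contact, inhalation of resuspended
    particulates), Monte Carlo propagation of exposure-parameter
    uncertainty with rank-correlation sensitivity analysis, screening-value
    exceedance and hotspot-area summaries, and a quadratic trend fit to
    yearly median log-concentrations. Includes a seeded lognormal
    synthetic-data generator that emulates the strongly right-skewed,
    industry-type-structured concentration data typical of national
    literature compilations, plus a command-line pipeline producing a
    reproducible end-to-end report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
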