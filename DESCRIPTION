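Package: metalrisk
Title: Probabilistic Health Risk Assessment of Toxic Metals in Drinking Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for carcinogenic and non-carcinogenic health risk
    assessment of toxic metals (Pb, Cr, Cd, Ni, As) in drinking water.
    Implements USEPA-style chronic daily intake for the ingestion and dermal
    contact routes, hazard quotient and hazard index, incremental lifetime
    cancer risk, Monte Carlo uncertainty propagation over declarative
    parameter distributions, guideline (EPA/WHO) exceedance screening,
    inverse-distance-weighted spatial interpolation of site concentrations,
    and a synthetic survey generator that reproduces published per-metal
    summary statistics for fully reproducible pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
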