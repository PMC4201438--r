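Package: mangrovesim
Title: Individual-Based Mangrove Stand Dynamics and Expert-Elicitation Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit, individual-based simulator of single-species
    mangrove stand dynamics built on the field-of-neighborhood (FON) competition
    formalism, with JABOWA-family diameter growth, suppression-driven mortality
    evaluated on a five-year growth memory, and stochastic seedling recruitment.
    Disturbance scenarios parameterized by expert-elicited impact intensity and
    spatial scale are imposed as a single killing event with reduced regrowth,
    and biomass recovery times are measured over replicated runs. Companion
    functions aggregate Delphi-style expert survey data: weighted Likert
    rankings, consensus species listing, plurality choices, and recovery
    timeframe stratification by development level.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
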