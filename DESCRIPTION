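Package: epsdigest
Title: Sequential Degradation Analysis of Extracellular Polymeric Substances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the stepwise enzymatic breakdown of extracellular
    polymeric substances (EPS) into progressively smaller, more broadly shared
    metabolites. Includes a synthetic multi-digest ion time-series simulator
    built on first-order depolymerization chains (Bateman kinetics),
    classification of untargeted LC-MS ion temporal profiles into decreased,
    bell-shaped and increased categories, m/z-binned category distributions and
    cross-digest sharing via ppm/retention-time feature alignment, exact-mass
    annotation against combinatorially enumerated peptides and amino-sugar
    catalogs, carbon mass-balance and EPS composition accounting with
    Coble-peak fluorescence integration, and community composition comparison
    (Bray-Curtis dissimilarity, fold changes versus an inoculum, Ward
    clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    readxl,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
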