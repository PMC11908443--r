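Package: hdallom
Title: Height-Diameter Allometry and Biomass Uncertainty for Tropical
    Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits and ranks ten candidate height-diameter models for
    tropical tree inventories by iterative nonlinear least squares,
    diagnoses fit quality (observed-versus-predicted regression,
    Graybill's joint F test, Theil's error decomposition, species
    random-intercept mixed models, phylogenetic generalized least
    squares), predicts heights with local and published
    (regional/pantropical) equations, propagates heights into tree- and
    plot-level aboveground biomass with log-bias correction factors, and
    decomposes height and biomass estimation error into total,
    systematic and random components by tree-size class. Includes a
    synthetic stand generator emulating size-stratified inventories of
    non-flooded (terra-firme) and seasonally flooded (varzea) Amazonian
    forests so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    lme4,
    minpack.lm,
    nlme,
    phytools,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
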