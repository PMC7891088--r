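Package: paleorange
Title: Climate-Stratified Ecological Niche Modelling of Species Range Change
Version: 0.1.0
Authors@R:
    person("Paleorange", "Developers", email = "paleorange@example.org",
           role = c("aut", "cre"))
Description: A seeded, fully synthetic-data-capable pipeline for reconstructing
    species range change across climatic time slices. From monthly climate grids
    it derives four bioclimatic variables (growing degree-days, temperature
    seasonality, aridity index, potential-evapotranspiration seasonality),
    builds an environmental stratification (PCA + k-means strata aggregated
    into warmth-ordered zones), fits a MaxEnt-style inhomogeneous Poisson
    point-process suitability model on presence and background cells with
    L1 regularization, derives an omission-controlled lowest-presence
    threshold, classifies per-stratum favourability under multiple
    pseudo-GCM climate scenarios with modal/joint/uncertain ensemble
    agreement, and reports latitude-weighted area change between time slices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
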