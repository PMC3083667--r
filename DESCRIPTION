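Package: tiedsim
Title: Agent-Based Simulation of Community Vulnerability to Climate Change
    Under Technology-Induced Environmental Distancing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates how a remote community's collective perception of
    climate change diverges from recorded change when technology-induced
    environmental distancing (TIED) erodes direct environmental exposure and
    local knowledge (LK) transfer counteracts that erosion. Provides a
    synthetic monthly climate forcing generator with trend, seasonality and
    noise; an age- and type-structured agent population with exponential
    mortality and constant-population replacement; exposure-gated known
    histories; weighted consensus aggregation of individual perceptions;
    six scenarios of declining traditional resource use; and replicate-averaged
    vulnerability time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
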