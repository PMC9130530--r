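Package: emsland
Title: Elements of Metacommunity Structure and Landscape Pattern Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analyses the structure of metacommunities from site-by-species
    incidence matrices using the Elements of Metacommunity Structure
    framework: reciprocal-averaging (correspondence analysis) ordination,
    coherence via embedded absences, species turnover via replacements,
    boundary clumping via Morisita's index of dispersion, Monte-Carlo
    significance against a fixed-site-richness equiprobable-species null
    model, and classification into the idealized distribution patterns
    (Clementsian, Gleasonian, nested, evenly spaced, checkerboard, random
    and their quasi-variants). Also provides species frequency and richness
    accounting for age-structured woody vegetation surveys,
    Fragstats-style categorical-raster landscape metrics (LSI, SHEI, AI,
    IJI, ENN, PARA, SHAPE), pairwise community similarity (Jaccard,
    Morisita-Horn) with great-circle distances, and synthetic generators
    for incidence matrices of known structure and toy rasters with
    closed-form metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
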