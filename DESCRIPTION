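Package: isoclim
Title: Bioclimatic Classification and Isobioclimate Change Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes Rivas-Martinez bioclimatic indices (continentality,
    ombrotype, thermicity and summer ombrothermic indices) from gridded
    monthly climate normals, classifies grid cells into isobioclimates from
    packaged category tables, and quantifies change between a present and a
    future climatology: per-index class-change maps, area-weighted transition
    matrices, novel and disappearing isobioclimate partitions, and
    climate-space summaries.  Includes gradient-plus-inverse-distance-squared
    (GIDS) statistical downscaling with moment-matching bias correction, a
    synthetic terrain/climate/vegetation generator for fully reproducible
    desk-scale experiments, and canonical correspondence analysis relating
    vegetation composition to the bioclimatic indices.  All gridded data are
    exchanged as tibbles of cell records and as plain-text ESRI ASCII rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
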