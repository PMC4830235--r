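Package: abindex
Title: Abundance Indices and Seasonal Movement Inference from Natural
    History Collection Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers population-level seasonal movement of a focal species
    from georeferenced natural history collection (museum specimen) records.
    Computes effort-corrected abundance indices (the proportion of focal
    specimens among all comparably collected specimens, per spatial unit and
    month), assigns records to a 5-arc-minute grid, named regions and
    seasonal periods, runs directional 2x2 chi-square tests of seasonal
    movement, and relates specimen localities to satellite greenness (EVI)
    through buffered raster extraction with random-location and weighted
    reference-subsample nulls. Includes a synthetic-data generator that
    emulates collector-effort clustering, seasonal regional occupancy and
    habitat preference, so the whole chain is testable against known truth.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
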