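Package: stemflux
Title: Stem CO2 Efflux, Dendrometer Partitioning and Drought-Effect Analysis for Coppice Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis chain for closed-chamber stem CO2 efflux and point
    dendrometer data in temperate coppice stands. Estimates stem CO2 efflux
    per wood volume and stem surface from 1-s chamber concentration traces
    via the ideal-gas closed-chamber equation, normalizes efflux to a
    reference temperature with a Q10 factor, partitions hourly dendrometer
    series into irreversible growth and tree water deficit with the
    zero-growth approach, derives vapour pressure deficit (Magnus formula)
    and gap-fills soil water content by per-treatment linear calibration,
    and quantifies drought effects as residuals and percent-of-expected
    relative to reference-year efflux-temperature regressions. Includes a
    seeded synthetic-data generator emulating a two-season (wet and
    drought) campaign design so every stage has ground-truth recovery
    tests, and a pipeline runner orchestrating all stages over CSV inputs.
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
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
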