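Package: wfcrop
Title: Green and Blue Crop Water Footprint Simulation and Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale crop water-footprint production chain: a daily
    crop-growth and vertical soil-water-balance simulator that traces green
    water (precipitation) and two blue water sources (irrigation and
    capillary rise) through the soil profile into crop water use, followed
    by census-based yield and area scaling, unit and production
    water-footprint accounting, coarse-to-fine allocation, weighted national
    and decadal aggregation, dataset writers, and the validation statistics
    used to compare gridded datasets. Includes a reproducible synthetic
    world generator (weather, soils, groundwater, crops, area maps, census)
    so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    ncdf4
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
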