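Package: grassocd
Title: Topsoil Organic Carbon Density Estimation for Grassland from Soil
    Profiles and NDVI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-method estimation of topsoil (0-30 cm) soil organic
    carbon density (SOCD) and stocks for steppe and meadow grassland.
    Implements pedotransfer bulk-density models with analytic inversion,
    depth-weighted gravel-corrected SOCD integration over a fixed layer
    scheme, NDVI maximum-value compositing and NDVI-driven SOCD mapping,
    per-pixel trend analysis (least-squares slope, Mann-Kendall test,
    Sen slope, five-level trend classification), zonal carbon stock
    accounting, point-to-grid interpolation (IDW and ordinary kriging),
    and Pearson correlation screening of environmental drivers.  A
    seeded synthetic-data generator emulates the soil-survey, satellite
    and plot-survey inputs so every stage is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
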