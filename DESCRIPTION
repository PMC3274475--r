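Package: gridshed
Title: Census-Unit Population Exposure Estimates from Gridded Air Quality Surfaces
Version: 0.1.0
Authors@R: person("Gridshed", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts daily gridded ambient-pollutant surfaces (concentration
    plus per-cell standard error) into census block-group estimates by
    inverse-squared-distance weighting over the four nearest grid centroids
    (Vincenty geodesic distances on WGS84), aggregates block-group estimates
    into population-weighted exposure series for tracts, counties, states and
    the nation with propagated standard errors, summarises exposures against
    daily NAAQS thresholds (exceedance days, percentile day-ranks, map class
    breaks, population at risk), and validates estimates against ground
    monitoring stations (MAD, Pearson correlation, absolute-deviation
    distribution). Includes a fully deterministic synthetic-data generator so
    the entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
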