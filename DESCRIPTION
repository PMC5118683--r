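Package: lcluc
Title: Land Cover Change Hotspot Detection from Annual Map Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects hotspots of land cover / land use change (LCLUC) from
    annual categorical land-cover map series. Maps are aggregated into big
    grid cells (10 x 10 pixels by default), per-cell per-class cover
    fractions are regressed on time by ordinary least squares, and cells
    with a significant slope (p < 0.1 by default) are reported as change
    hotspots, with net change (slope x interval x cell area) and its one
    standard deviation (slope standard error x interval x cell area).
    Includes zonal gain/loss accounting over biome-style overlays, a
    consensus/Bayesian-averaging fusion rule for multi-classifier map
    ensembles, an endpoint-differencing baseline, and a synthetic landscape
    scenario generator with analytic ground truth for validating the whole
    pipeline without satellite data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
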