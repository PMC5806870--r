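Package: sedscape
Title: Watershed Soil Loss, Sediment Routing, and Restoration Scenario Analysis
Version: 0.1.0
Authors@R:
    person("Posse", "Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for long-term annual sediment budgeting in small rural
    watersheds. Implements USLE soil loss on a gridded terrain, single
    flow-direction (D8) routing of eroded sediment with per-pixel vegetative
    trapping, rainfall-erosivity estimation from multi-gauge daily
    precipitation, stage-discharge-turbidity rating curves for observed
    sediment export, an ensemble trial-and-error calibration of cover and
    retention parameters, and gradual land-use restoration scenarios
    (riparian buffers, steepest slopes, and their combination) compared on
    soil loss and sediment export. A fully synthetic watershed generator
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
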