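Package: heatbudget
Title: Pedestrian Energy Budgets and Urban Cooling Design Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Steady-state human energy-budget (COMFA-style) modelling of
    pedestrians in urban micro-environments, driven by hourly station
    weather and census-tract land-cover composition. Computes baseline and
    land-cover-weighted predicted energy budgets over the hottest daytime
    window, applies "cooling" landscape design scenarios (tree-canopy
    addition, asphalt-to-concrete surface swaps), compares existing and
    proposed designs, ranks tracts, and relates energy budgets to
    heat-related emergency medical response call counts during extreme
    heat events. Includes seeded synthetic generators for weather,
    land-cover rasters and call counts so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
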