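Package: ecoplateR
Title: Kinetic Community-Level Physiological Profiling of Biolog EcoPlates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for Biolog EcoPlate optical-density time
    series from microbial community samples: blank subtraction and replicate
    averaging, cubic-spline interpolation on a 96-hour grid, Gompertz
    growth-curve fitting with spline fallback, activity integrals (area under
    the curve), aggregation into five substrate guilds, baseline scaling and
    min-max normalization, and a multilinear model linking carbohydrate and
    polymer utilization to solid-waste biodegradability measured as the
    four-day respiration index. Includes a synthetic-data generator that
    emulates a nine-reactor landfill in-situ aeration experiment so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    car,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml,
    jsonlite
Config/testthat/edition: 3
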