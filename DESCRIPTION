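Package: landes
Title: Agent-Based Ecosystem Services Modelling on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated, cell-based modelling system for quantifying
    multiple ecosystem services and their response to land-use decisions on
    a uniform grid of quarter-section-scale cells holding fractional
    landcover composition. Couples a forest timber and carbon model (stand
    growth/carbon curves, mill agents scheduling harvest within Forest
    Management Units under the Annual Allowable Cut, least-cost timber
    transport, clearcut and variable-retention modes), an annual
    water-purification model (D8 overland-flow routing over a sink-filled
    DEM, export-coefficient nutrient loading, RUSLE erosion, landcover
    retention, river-network accumulation at monitoring points, Latin
    hypercube calibration), a pollination model (nesting-habitat driven
    canola yield uplift over a 4-year rotation), and a
    biodiversity-intactness index regressed on human footprint; scenario
    engines compare harvest strategies and sweep incremental agricultural
    expansion. Includes a synthetic-landscape generator so every component
    is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
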