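Package: ecocircuit
Title: Ecological Security Patterns from Circuit Theory and Least-Cost Corridors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Raster-native toolkit for landscape ecological security pattern
    analysis: InVEST-style habitat quality modelling and ecological source
    extraction, landscape pattern metrics with granularity backstepping,
    species-group resistance surfaces combined by a cellwise maximum rule,
    cost-weighted distance corridors with key/potential classification,
    circuit-theory current mapping with pinch-point extraction, moving-window
    barrier detection scored by least-cost-distance improvement, and rule-based
    four-class protection zoning with buffers and area accounting. Includes a
    seeded synthetic landscape generator so the full pipeline runs end-to-end
    without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
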