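Package: tomcan
Title: Dynamic Functional-Structural Model of a Tomato Canopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates single-stem tomato canopies day by day from greenhouse
    climate drivers. Organ-level models describe thermal-time driven leaf and
    internode growth, leaf shape, appearance and senescence; plants are
    assembled into explicit 3D triangle scenes (rhombus leaflets, cylinder
    internodes, 144 degree phyllotaxis); a quasi-Monte-Carlo path tracer
    computes per-leaf absorbed light, ground-sensor transmission and
    Beer-Lambert extinction coefficients; dry mass follows from absorbed light
    through a light-dependent light-use efficiency. A scenario engine scales
    architectural traits (leaf angle, curvature, internode length, leaflet
    arrangement) to quantify their effect on shoot dry mass under contrasting
    temperature regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
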