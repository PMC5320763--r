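Package: casemap
Title: Case-Based Species Distribution and Coverage Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Similarity-based (case-based) prediction of species occurrence
    and coverage over a regular grid. Implements a weighted variant of
    Gower's similarity for mixed numeric and categorical site features,
    with machine-learned feature weights, exemplar weights and a similarity
    budget; spatial partitioning of a study area into proved-absence,
    probable-presence and unclear regions, each with its own predictive
    set; neighbourhood autocovariates and 50 m record thinning; and
    production of coverage, decision-certainty and mean-similarity raster
    maps. Includes a synthetic-landscape generator so the whole pipeline
    can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
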