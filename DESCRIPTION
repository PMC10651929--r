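Package: mobifood
Title: Mobility-Derived Fast Food Exposure and Diet-Related Disease Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline linking smartphone-mobility-derived fast food
    outlet visit measures to survey-reported fast food intake and diet-related
    disease. Clusters raw geolocation pings into stays with a greedy
    median-centroid algorithm, attributes stays to points of interest by
    nearest-neighbour haversine matching, computes per-user fast food visit
    metrics, aggregates them into neighborhood-level contextual variables,
    links them to survey respondents, and fits multinomial and binary logistic
    regression models compared by Akaike weights. Includes a synthetic-world
    generator with planted parameters for end-to-end validation, and the
    temporal-stability and confounder sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    geosphere,
    jsonlite,
    mgcv,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
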