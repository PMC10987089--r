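Package: affbound
Title: Affordance Boundary Analysis for Object-Action Judgment Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Characterizes the boundary in perceived object affordances that
    tracks an agent's body size. From binary object-action judgments the
    package builds per-object affordance vectors (endorsement proportions over
    a fixed action list), an object-by-object representational similarity
    matrix with hierarchical clustering, a neighboring-size-rank similarity
    curve, a permutation-tested trough statistic that localizes the boundary,
    dependent-correlation comparisons (Steiger's Z, Zou's interval) with
    normal-prior Bayes factors, and an object-level boundary-location
    estimate. A synthetic judgment generator emulating agents of configurable
    body size makes every stage verifiable without collected ratings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
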