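Package: schoolfeed
Title: Individual-Based Feeding and Growth Simulation for Fish Schools
    in Aquaculture Tanks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a boid-style schooling model of fish swimming in a
    cylindrical rearing tank with a feed-conversion growth model.  Sinking
    feed pellets are broadcast daily over a square of configurable size,
    per-individual pellet intake is resolved by contact during a simulated
    feeding bout, and daily intake drives body-mass growth through an
    allometric length-mass relationship.  The package quantifies how the
    spatial footprint of feed delivery shapes the variance and skewness of
    the final body-mass distribution, and provides seeded, replicable
    multi-method comparison experiments with ledger export and summary
    statistics (Kruskal-Wallis location test, Bartlett variance test,
    distribution skewness).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
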