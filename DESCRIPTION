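Package: oversweet
Title: Mining Consumer Food Reviews for Sweetness Perception
Version: 0.1.0
Authors@R:
    person("Review", "Miner", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for mining consumer reviews of food products for
    sweetness perception. Tags sweetness-level phrases (oversweet,
    under-sweet, neutral) with negation and exclusion handling, classifies
    whether an oversweet phrase refers to the purchased product using a
    bag-of-words gradient-boosted classifier, links reviews to product
    ingredient lists via a sweetener ontology, and tests per-sweetener
    enrichment (proportion tests, Bonferroni), product-level rating gaps
    (one-sided Wilcoxon rank-sum, Benjamini-Hochberg), and per-customer
    dispersion. Ships a synthetic review-corpus generator with planted
    ground truth so every pipeline stage is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
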