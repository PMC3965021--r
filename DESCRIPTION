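Package: funclink
Title: Construction, Integration and Evaluation of Cofunctional Gene Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building probabilistic functional gene networks from
    heterogeneous evidence. Raw evidence (co-expression, phylogenetic
    profiles, co-citation, or externally supplied scores) is calibrated into
    log-likelihood scores (LLS) by rank-binned benchmarking against a
    pathway-derived gold standard, data-specific networks are integrated by
    rank-decay weighted summation, and networks are assessed with cumulative
    binned precision-recall curves and leave-one-out guilt-by-association
    ROC analysis. Includes network-guided hypothesis-generation tools
    (candidate pathway members, neighbor-based function inference,
    hypergeometric modulator search) and seeded synthetic-data generators
    with planted structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
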