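Package: pathscreen
Title: Cross-Platform Drug Screen Analysis with Evidence-Scored Interactome Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts per-drug protein pathway networks from an
    evidence-scored protein-protein interactome by propagating path-product
    evidence scores from drug targets and selecting an empirical score
    threshold, associates the networks with disease phenotypes through
    one-sided Fisher exact tests filtered against random-network nulls and
    Benjamini-Hochberg correction, relates network-protein membership to
    drug screen outcomes with L2-regularized regression calibrated by
    permutation nulls, runs local Fisher-exact gene-set enrichment on
    extreme-coefficient genes, and computes cross-screen consensus genes
    and terms.  A synthetic-data generator with planted gene-level effects
    makes every stage testable without restricted source data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
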