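Package: herdstruct
Title: Multilevel Social Structure from Collective Movement of Harem-Living Equids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer multilevel social organisation (families within
    harems within a herd) from fine-scale collective-movement trajectories and
    long-term demographic monitoring of harem-living equids such as
    Przewalski's horses. Computes dyadic movement variables (session-averaged
    pairwise distance and delayed directional-correlation movement
    similarity), detects social levels from the bimodal pairwise-distance
    distribution, classifies individuals into harems from movement alone,
    builds two-layer proximity networks with minimum-spanning-tree critical
    thresholds and closeness centrality, derives pedigree kinship classes,
    familiarity (shared harem days), female transfer counts, Jaccard-based
    harem lineages and stallion harem-keeping experience, and provides the
    seeded randomisation-test framework (two-sample, paired, correlation and
    roster-reassignment schemes) used to relate movement to demography. A
    synthetic herd and population generator with full ground truth supports
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    withr,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
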