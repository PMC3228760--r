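Package: scortho
Title: Single-Copy Ortholog Discovery by Gene-Tree/Species-Tree Reconciliation
Version: 0.1.0
Authors@R:
    person("scortho", "maintainers", email = "scortho@example.org", role = c("aut", "cre"))
Description: Identifies genes that have remained in single copy since a focal
    ancestor by duplication-loss parsimony reconciliation of gene trees
    against guide species trees. Gene trees are collapsed at a bootstrap
    support threshold, every rooting is assessed, unresolved branches are
    treated as soft polytomies and refined at minimal cost, and single-copy
    sub-trees are extracted from multigene families with a configurable
    tolerance for species-specific duplications and losses. Also provides
    the classical taxon-count baseline with a one-genome tolerance, pooling
    of calls across competing guide trees, completeness assessment of gene
    sets against a single-copy reference, and a birth-death simulator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    optparse
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
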