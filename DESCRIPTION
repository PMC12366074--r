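Package: plrdist
Title: Path-Label Reconciliation Dissimilarity for Reconciled Gene Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares gene trees that have been reconciled with a common
    species tree, taking into account tree topology, ancestral gene-species
    maps and duplication/speciation event labels simultaneously. Implements
    the path-label reconciliation (PLR) semi-metric with a tunable weight
    between its species-path and event-label components, least
    duplication-resolved normal forms obtained by contracting redundant
    duplication edges, closed-form diameters for normalization, a bottom-up
    simulator of random reconciliation scenarios on a fixed leaf set, and an
    evaluator that ranks all rootings of an unrooted gene tree against a
    reference reconciliation. Reconciled trees are read and written as
    rooted Newick with NHX-style species and event annotations.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
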