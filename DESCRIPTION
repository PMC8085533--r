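Package: coexcerna
Title: Weighted Co-Expression Modules, Hub lncRNA Stability and ceRNA
    Networks from Expression Matrices
Version: 0.1.0
Authors@R:
    person("coexcerna", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a microarray lncRNA profiling
    workflow: probe re-annotation from alignment tables, empirical-Bayes
    moderated differential expression, weighted gene co-expression network
    construction (soft thresholding, topological overlap, module detection,
    eigengenes, module membership and trait association), permutation-based
    module preservation (Zsummary and medianRank), bootstrap and
    parameter-sweep stability of hub lncRNAs, hypergeometric shared-miRNA
    ceRNA network inference, and bench diagnostics (ROC/AUC and
    2^-delta-delta-Ct relative quantification). Includes a synthetic-data
    generator with planted modules, hubs and ceRNA pairs so that every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
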