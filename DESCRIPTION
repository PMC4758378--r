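Package: uprhd
Title: Detecting Unfolded Protein Response Activation in Huntington's Disease Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for detecting coordinated activation of
    the unfolded protein response (UPR) in Huntington's disease (HD) expression
    data. Provides from-scratch gene-set enrichment analysis (weighted
    Kolmogorov-Smirnov running sum, permutation null, normalized enrichment
    scores, empirical FDR and leading-edge extraction), cross-model consensus
    signatures, stress-response-element (UPRE/ERSE) promoter scanning with
    analytic chance-hit calibration, hypergeometric/Fisher over-representation
    statistics with Benjamini-Hochberg adjustment, per-gene Spearman correlation
    of expression with CAG repeat length under a per-gene permutation FDR, and
    protein-interaction network overlay with tri-set prioritization of UPR-HD
    connector genes. Ships synthetic-data generators with recorded ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
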