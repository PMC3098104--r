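Package: lincontig
Title: Linear-Topology Contig Assembly from BAC Clone Restriction Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles BAC clones into ordered contigs from (high information
    content) restriction fingerprints. Implements Monte-Carlo calibrated
    overlap p-value metrics that improve on the classical Sulston score,
    temporal exclusion of clones and clone overlaps not proven by parallel
    paths (TENPP), single-linkage clustering with an adaptively tightening
    significance cutoff, diagnosis of the topological linearity of contigs via
    diametric paths and vertex ranks, clone ordering by an open-path traveling
    salesman criterion with jackknife stability assessment, contig merging and
    minimal tiling path selection, and verification of externally built
    contigs. A BAC-library simulator (in-silico restriction digestion, clone
    sampling, chimeras, band-scoring noise) provides ground truth for
    validation, together with partition-comparison statistics (Rand index,
    mean cluster overlap).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
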