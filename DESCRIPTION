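Package: astromyc
Title: Proximal MYC Network Alterations and 19q Microdeletion Analysis in
    IDH-Mutant Astrocytoma
Version: 0.1.0
Authors@R:
    person("Astromyc", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-level somatic copy-number alteration (SCNA) calling from
    segmented copy-number data, proximal-MYC-network (PMN) hit annotation, a
    stratified Monte-Carlo permutation test for SCNA enrichment in a gene
    set, a two-filter expression/alteration screen for candidate MYC
    regulators in PMN-wild-type tumours, minimal-common-region (MCR)
    discovery over recurrent loss segments, genomic-instability metrics
    (wGII, CAER, chromothripsis flag), three-way tumour subclassification
    with associated bulk statistics (linear model, Cochran-Armitage trend,
    Fisher exact, log-rank), and a per-region Poisson interaction model
    linking single-cell copy-number estimates to MYC counts. Ships a
    synthetic-data generator that plants the cohort structure these analyses
    assume so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
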