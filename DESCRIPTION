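Package: ssrkit
Title: Dominant-Scored Polyploid SSR Fingerprinting for Genebank Collections
Version: 0.1.0
Authors@R:
    person("CIP Genebank Informatics", role = c("aut", "cre"),
           email = "genebank-informatics@example.org")
Description: Tools for managing and analysing dominant (presence/absence)
    simple sequence repeat (SSR) fingerprints of polyploid clonal crops, as
    used in genebank collection management. Provides a binary allele-matrix
    data model with block-level missing data, per-marker diversity
    statistics (allele counts, equal-dosage allele frequencies,
    polymorphism information content, expected heterozygosity, Fst),
    Jaccard dissimilarity, neighbor-joining trees with Newick export,
    principal coordinates analysis, similarity-threshold redundancy
    pruning, paired true-to-type identity verification, cross-collection
    reconciliation, and a structured-population hexaploid fingerprint
    simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
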