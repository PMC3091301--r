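Package: regulonscan
Title: RIP-Chip Target Calling, Trinucleotide-Repeat Motif Scanning and
    RNA Regulon Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for defining the RNA regulon of an
    RNA-binding protein from two-color array data. Implements SAM-style
    permutation false-discovery-rate calling of affinity-enriched
    transcripts, maximal degenerate trinucleotide-repeat scanning with
    transcript-region and codon-frame resolution, hypergeometric and
    minimum-hypergeometric gene-set enrichment with Bonferroni control,
    and expression-shift analysis of target subsets within Gene Ontology
    terms from matched mRNA and protein log-ratio tables. Ships seeded
    synthetic-data generators that emulate the assumed data structure
    (planted targets, planted in-frame repeats, planted subset shifts)
    so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
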