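Package: txeval
Title: Evaluation of De Novo Transcriptome Assemblies with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating de novo transcriptome assemblies against a
    reference proteome: digital normalization of reads by median k-mer
    abundance with low-abundance k-mer trimming, contig descriptive
    statistics and length histograms, subject-coverage evaluation of BLAST
    tabular hits at CDS reconstruction levels with ortholog-based gene
    grouping, gene-level TPM quantification with cross-library core
    expressed-gene sets and hypergeometric fold-enrichment, plus a
    synthetic-data generator that plants known reconstruction fractions,
    core genes and read depths so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
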