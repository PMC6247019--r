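Package: cofit
Title: Conditional Fitness Profiling from Transposon Insertion Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative fitness profiling from transposon insertion
    sequencing (Tn-seq) of Himar1 mariner libraries passaged under
    selection. Estimates per-insert serial-passage fitness from TA-site
    read counts corrected by the population expansion factor, aggregates
    to gene level, classifies genes as detrimental, beneficial, neutral,
    lethal or insufficient, and compares fitness across selection arms
    and strains to call conditionally important genes. A companion
    transcriptomics arm filters count matrices, runs a negative-binomial
    Wald test for differential expression with Benjamini-Hochberg FDR,
    and computes cross-stressor response overlap and fitness-expression
    concordance. Includes a synthetic-data generator (genomes, insertion
    libraries evolved under selection, stressor-response RNA-seq counts)
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
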