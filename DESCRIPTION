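Package: cueditscan
Title: Prediction of APOBEC3A/G C-to-U RNA Editing Sites in Coding
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts cytosines in mRNA coding sequences that are likely
    substrates of APOBEC3A/APOBEC3G C-to-U RNA editing.  Combines a
    rules-based scorer for GC-rich stem-loop (hairpin) structures with a
    random-forest classifier over binary-encoded 25-nucleotide sequence
    windows, and merges the two by union or intersection consensus.
    Includes an imbalance-aware benchmarking harness (recall, precision,
    F1, MCC, AUROC, AUPRC against the prevalence baseline, and a pairwise
    window-identity redundancy audit), a ClinVar-style variant pipeline
    that filters non-synonymous SNPs, validates them against coding
    sequences, infers mRNA-level C-to-U changes and bins clinical
    significance, a MeSH-style hierarchy rollup for disease association
    counting, and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
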