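Package: ucfrag
Title: Fragmentomics of Urinary Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for urinary cell-free DNA (ucfDNA)
    fragmentation features: fragment-size histograms and size-bin
    proportions, 4-mer end-motif spectra with rankings and rank
    concordance, the jagged-end index computed from bisulfite
    methylation calls (JI-U), fragment-end density around DNase I
    hypersensitive sites (DHSs) with median normalization, and
    subject-level classification by Mann-Whitney tests, ROC/AUC and
    leave-one-out linear support vector machines. Includes a seeded
    synthetic-data generator (genome, DHS intervals, genotype-preset
    fragment samples, methylation-call tables, two-group cohort
    feature tables) calibrated so that every pipeline stage is
    verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
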