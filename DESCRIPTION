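Package: pepselect
Title: Substrate Profiling of Peptide Display Selections from Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of single-round peptide display selection experiments
    profiled by paired-end sequencing. Turns raw FASTQ from before- and
    after-selection samples into filtered peptide count tables (adapter
    trimming, mean-quality filtering, in-read tag demultiplexing, anchor-based
    extraction of the peptide-coding region, translation and library-design
    filters), computes per-peptide and per-position amino-acid enrichment
    factors with ranking and heatmap-derived consensus sequences, and ranks
    position-residue indicators by cross-validated random-forest permutation
    importance with Pearson-based signs and hydrophobicity/polarity group
    comparisons. Includes a selection-experiment simulator (uniform NNK codon
    sampling, logistic-additive capture model with nonspecific background and
    optional bead-binding artifacts, paired-end read emission with
    substitution errors) so every stage can be verified by parameter recovery
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
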