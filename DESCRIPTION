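Package: promotif
Title: Attention-Guided Motif Discovery for Tissue-Specific Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing tissue-specific promoter classification
    datasets with two negative-set designs (random non-promoter windows and
    GC/repeat-matched genomic nulls), and for interpreting sequence
    classifiers through an attention-guided motif discovery pipeline:
    per-layer [CLS]-to-token attention aggregation, candidate motif
    selection, Aho-Corasick multi-pattern occurrence counting,
    hypergeometric enrichment with Benjamini-Hochberg correction, gapless
    motif merging, Kernel SHAP token attribution with per-token summary
    statistics, and TSS-relative positional profiling with binned attention
    and kernel density estimates. A deterministic toy attention provider and
    a seed-reproducible planted-motif simulator make every stage testable
    without a trained model or a reference genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Biostrings,
    IRanges,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
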