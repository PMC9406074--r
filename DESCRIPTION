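Package: plasmavar
Title: Haplotype-Based Low-Frequency Variant Calling and Prognostics for
    Plasma cfDNA Amplicon Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ultra-deep amplicon sequencing of plasma cell-free
    DNA (cfDNA): paired-end read merging, quality filtering and primer
    demultiplexing; haplotype collapsing with per-strand abundance and
    strand-concordance filters; single-nucleotide variant calling with
    aggregate frequency thresholds and genomic labelling; per-sample
    mutational-burden metrics; and cohort-level prognostic statistics
    (Mann-Whitney comparisons, ROC with Youden cut-offs, Kaplan-Meier and
    log-rank analysis, Cox proportional-hazards models with biomarker
    dichotomizations). Includes a seeded simulator for amplicon panels,
    paired-end reads with spiked-in variants, and clinical cohorts, so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    survival,
    stats,
    tools,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    readr
Config/testthat/edition: 3
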