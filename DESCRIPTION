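Package: promptscape
Title: Discovery and Characterization of Promoter Upstream Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for genome-wide discovery and
    characterization of promoter upstream transcripts (PROMPTs), the long
    noncoding RNAs transcribed within a short window upstream of
    protein-coding transcription start sites. Covers lncRNA filtering
    (length, longest ORF, coding potential), PROMPT classification against
    an annotation, FPKM quantification and negative-binomial differential
    expression, PROMPT-gene expression correlation, Z-score co-expression
    networks with greedy module extraction and hypergeometric GO enrichment,
    thermodynamic RNA secondary-structure analysis (MFE folding via
    ViennaRNA, loop/stem element annotation, loop-localized motif
    enrichment, SNP and loop-mutant energy effects), and population
    statistics (haplotype frequencies, linkage disequilibrium, tissue
    specificity tau, and substitution-rate ratios against ancestral
    repeats). Ships synthetic-data generators with known ground truth for
    every input so the whole pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
SystemRequirements: ViennaRNA (RNAfold and RNAeval on the PATH)
Config/testthat/edition: 3
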