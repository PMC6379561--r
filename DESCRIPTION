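Package: dmrkit
Title: Window-Based Differential DNA Methylation and Transgenerational
    Multi-Omic Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for MeDIP-seq style differential DNA
    methylation between two lineages: fixed-width genome tiling, CpG
    content annotation, TMM-normalized negative-binomial exact testing of
    window counts, differentially methylated region (DMR) construction by
    seed thresholding with edge extension, DMR feature summaries and
    chromosomal clustering, differential-expression calling for mRNA,
    lncRNA and small noncoding RNA count tables, genomic overlap and gene
    association analysis, and a histopathology disease-frequency statistic
    based on mean-plus-2SD observer cutoffs with consensus calling and
    Fisher's exact test. Includes a fully seeded synthetic-data generator
    with known ground truth (planted DMRs, planted differential
    expression, planted disease excess) for end-to-end validation of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
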