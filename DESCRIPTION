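Package: tgscan
Title: Transgene Insertion-Site Detection and Characterization from
    Paired-End Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize a transgenic plant line from paired-end
    DNA and RNA sequencing alignments: localization of transgene integration
    sites from bridging read pairs and split (chimeric) reads with base-pair
    junction calling and lesion inference; detection of transgene-host fusion
    transcripts, per-exon coverage profiling and disruption-zygosity calls;
    pileup genotyping with genomic and transcriptomic variant filter
    cascades, consensus-error subtraction, Ti/Tv and CDS-restricted SNV
    density estimation; fragment counting, FPKM/TPM with a sample-specific
    expression threshold and log2-fold-change gates; gene-set QC filters,
    summary metrics and a tiered homology-annotation cascade. A synthetic-data
    module generates host genomes, insertions, variants and read sets with
    exact truth tables so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
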