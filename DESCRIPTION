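Package: scmethkin
Title: Kinetics of De Novo DNA Methylation from Single-Cell Bisulfite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of single-cell bisulfite sequencing of
    developing male germ cells: per-cell quality control (bisulfite
    conversion rate from an unmethylated lambda spike-in, CpG coverage
    rate, somatic-cell contamination flagged at maternally methylated
    imprinted DMRs), grouping of cells by global CpG methylation level,
    genome-tile kinetic scoring and fast/intermediate/slow classification
    of methylation acquisition, annotation enrichment tests, context and
    non-CpG trinucleotide motif profiles with active-region masking, and
    expression correlates of gene-body methylation speed. Ships a
    synthetic-cohort generator with planted ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    Biostrings,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
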