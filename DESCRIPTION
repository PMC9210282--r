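Package: haplographr
Title: Gene-Anchored Haplotype Graph Imputation from Low-Coverage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a practical haplotype graph for inbred plant panels:
    gene-anchored reference ranges, per-taxon haplotype ingestion from
    gVCF-style variant calls, divergence-threshold consensus collapsing,
    k-mer pseudo-alignment of low-coverage reads to consensus haplotypes,
    and hidden-Markov-model path decoding to impute genotypes at all
    catalogued sites. Includes the matching evaluation protocol (coverage
    down-sampling arithmetic, in-silico restriction digest target sizing,
    genotype concordance with MAF- and genome-stratified accuracy),
    population-genetic summaries (sliding-window nucleotide diversity and
    Tajima's D, MAF spectra, LD decay and LD-based marker pruning), and a
    seeded synthetic-data generator producing founder panels with a
    divergent introgression donor, recombinant inbred lines, and
    capture-, GBS- and skim-style read sets with truth genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
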