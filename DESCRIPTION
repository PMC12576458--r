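Package: hybridpop
Title: Population Genomics of Homoploid Hybrid Speciation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for establishing and dissecting the homoploid hybrid origin
    of a diploid species from resequencing and allele-resolved expression data.
    Implements sliding-window diversity and differentiation scans (nucleotide
    diversity, Hudson's Fst, reduction of diversity, z-score candidate calling),
    the four-taxon ABBA/BABA D statistic with block-jackknife significance,
    diagnostic-SNP discovery and gene-level allele-specific expression (ASE)
    testing with a consistent / direction-shifting / non-directional
    classification, a per-gene Hudson-Kreitman-Aguade (HKA) scan for positively
    selected genes, chromosomal-inversion genotyping from diagnostic-site
    heterozygosity with inside-versus-outside linkage-disequilibrium contrasts,
    and a seeded synthetic-data generator (Balding-Nichols populations, planted
    introgression, sweeps, inversions and allelic bias) with ground-truth
    records so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
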