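Package: latscan
Title: Latitude-Driven Selection Scans from Population SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide scan for latitude-driven adaptation from
    multi-population diploid SNP genotypes. Computes per-SNP Weir-Cockerham
    fixation indices (F_ST) across populations, sample-size-weighted Pearson
    correlations between ancestral-allele frequency and absolute latitude,
    and a two-step empirical top-decile selection (autosomes and X handled
    separately) yielding a set of latitude-related genes. Includes gene-set
    overlap enrichment against a fixed gene universe (hypergeometric tests
    with Bonferroni adjustment), a non-synonymous excess test, a gene-length
    bias check, a Balding-Nichols synthetic-panel generator with planted
    latitudinal clines for end-to-end validation, and readers for
    tab-separated genotype matrices, PLINK-style ped/map files and minimal
    VCF.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
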