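Package: giftpath
Title: Genotype-Phenotype Association Mapping with Genetic Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Association mapping for quantitative traits using genetic paths:
    cumulative sums of genotype microstates ordered by phenotypic residual rank
    (the GIFT approach). Provides microstate encoding of diploid genotype calls,
    construction of per-SNP genetic paths and their permutation null ensemble, a
    combinatorial path p-value based on multinomial arrangement counting within
    extremum-delimited path regions, empirical significance-threshold calibration,
    Benjamini-Hochberg false-discovery-rate adjustment, a conventional
    single-marker ordinary-least-squares baseline with gene-effect and dominance
    estimates, SNP quality-control filters (minor allele frequency, call rate,
    Hardy-Weinberg exact test) with greedy linkage-disequilibrium pruning, and
    seeded simulators for additive, null, and scale-dependent (sign-flipping)
    genetic architectures. Genotypes are read from a tab-separated dialect, VCF,
    or PLINK ped/map files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
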