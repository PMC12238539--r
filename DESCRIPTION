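Package: polygp
Title: Genomic Prediction with Multi-Allelic Variants in Mixed-Ploidy Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ridge-regression BLUP (rrBLUP) genomic prediction in
    diversity panels that mix ploidy levels (tetraploid and octoploid
    individuals) and variant allelic complexities. Octoploid genotype calls are
    collapsed to pseudo-diploid pairs, multi-allelic SNPs and indels are
    expanded into per-alternative-allele indicator columns coded {1, 0, -1},
    and models are evaluated under a stratified train/test split with repeated
    5-fold cross-validation against a population-structure (principal
    component) baseline, yielding the accuracy improvement statistic
    r2_i = r2_g - r2_p. Includes balanced marker down-sampling with paired
    Wilcoxon comparisons, gene-coverage counting with z-score placement,
    coefficient-based variant importance with benchmark-gene Fisher
    enrichment, per-allele phenotype contrasts, and a seeded simulator of
    structured mixed-ploidy panels for end-to-end validation.
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
    rtracklayer,
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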