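Package: phenosel
Title: Phenomic-Assisted Seed-Yield Selection for Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for phenomic-assisted selection of seed
    yield in multi-environment plant breeding trials. Provides a synthetic
    trial generator with known genetic architecture (hyperspectral canopy
    reflectance, canopy traits, SNP genotypes, alpha-lattice yield plots),
    plot-quality filtering and repeatability-based waveband selection,
    REML mixed-model BLUP preprocessing, genomic-relationship-matrix
    heritability and genetic correlations, random-forest yield rank
    prediction under breeding cross-validation scenarios, genetic-algorithm
    waveband optimization for multispectral sensor design, and
    selection-intensity classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    lme4,
    ranger,
    yaml,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
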