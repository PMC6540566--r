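Package: groupedscore
Title: Efficient Score Tests for Grouped Failure-Time Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-interval (grouped) failure-time proportional-hazards
    modelling for genome-wide variant scans. Implements the grouped-data
    likelihood with baseline interval survival probabilities, maximum
    likelihood estimation of the nuisance parameters under the null, a
    partitioned efficient score test per variant with asymptotic chi-square
    p-values, per-variant effect-size estimation, Bonferroni and Storey
    q-value multiple-testing adjustment, kernel-based gene/pathway set
    statistics built from per-sample score contributions, and a simulator
    plus operating-characteristics harness for type-I-error, bias and power
    studies. Readers for delimited, PLINK BED and VCF dosage genotypes are
    included, together with a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
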