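Package: famscore
Title: Family-Based Rare-Variant Association Testing with
    Kinship-Structured Score Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-level rare-variant association testing for related
    (family-based) samples. Provides pedigree-based kinship and
    genotype-based relatedness matrices, family-aware quality control and
    expected-dosage imputation, restricted-maximum-likelihood null models
    with a polygenic covariance kernel, and quasi-likelihood score tests
    for correlated subjects: a weighted burden test, a variance-component
    kernel (SKAT-type) test, an omnibus test interpolating the two, and a
    variable-threshold statistic with a Monte-Carlo null. A gene-dropping
    pedigree simulator generates genotypes and phenotypes with the
    covariance structure the tests assume, and drives built-in type-I
    error calibration and power experiments.
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
    rlang,
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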