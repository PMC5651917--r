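Package: cvherit
Title: Cross-Validated Heritability and Predictability for Genomic Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic selection with the GBLUP mixed model: marker-inferred
    kinship with trace rescaling, restricted maximum likelihood (REML)
    variance components via an eigendecomposition profile likelihood,
    best linear unbiased estimation and prediction through Henderson's
    equations, and conditional-expectation prediction of genetic values
    for held-out individuals. The central feature is k-fold
    cross-validated heritability (Hcv) and predictability (Pcv), which
    control the overfitting of heritability caused by the many
    trait-irrelevant markers entering whole-genome fits, together with a
    recombinant-inbred-line population simulator, a line-plus-replicate
    ANOVA heritability baseline, and drivers for the simulation
    experiments that contrast the estimators.
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
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
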