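Package: pubertwin
Title: Twin Modeling of Puberty Timing and Body Mass Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the genetic and environmental overlap between
    puberty timing and body mass index with the classical twin design. Provides
    a synthetic twin-cohort generator with configurable additive-genetic,
    shared-environmental and unique-environmental variance components,
    cross-trait component correlations, right-skewed BMI, right-censored
    pubertal age and wave-specific attrition; full-information maximum
    likelihood univariate and bivariate Cholesky ACE/ADE/AE models with
    genetic and environmental correlations and trait-correlation
    decompositions; cluster-robust standardized regression for longitudinal
    baseline-adjusted associations and polygenic-score analyses; and a
    pipeline that turns a cohort into publication-style summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
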