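Package: gibnet
Title: Genetically Informed Brain Networks from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers latent genetic factors ("genetically informed brain
    networks") underlying the genetic covariance of many GWAS phenotypes.
    Estimates heritabilities and genetic covariances by LD score regression
    with a shared block-jackknife sampling covariance, runs an exploratory
    factor analysis on the odd-chromosome covariance and a diagonally
    weighted least squares confirmatory factor analysis on the
    even-chromosome covariance, prunes and selects factor models by AIC,
    performs a multivariate GWAS of each latent factor, tests overlap
    between factor region sets and arbitrary parcellations with a
    Dice-coefficient permutation null, and estimates cross-trait genetic
    correlations. Includes a summary-statistic simulator with known
    factor-structured genetic covariance so every stage can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
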