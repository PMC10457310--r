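Package: gxeblock
Title: Block-Partitioned Regression Estimation of Heritability and
    Gene-Environment Interaction Variance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the genome-wide variance of a complex trait explained
    by additive genetic effects (SNP heritability) and by gene-by-environment
    interactions using block-partitioned multiple linear regression on
    individual-level genotype data. Genotypes are quality-filtered,
    standardized and split into chromosome-bounded blocks small enough that
    the sample size exceeds ten times the predictor count; adjusted R-squared
    values from per-block least squares (direct QR or conjugate-gradient
    solvers) are summed genome-wide, with asymptotic variances of the squared
    multiple correlation from the exact Kendall-Stuart moments and Wald
    confidence intervals. Includes a liability-scale transformation for
    dichotomous outcomes, an LD-structured synthetic genotype generator, a
    twelve-scenario simulation validator covering collider structures and
    non-normal interaction effects, a non-central-F power calculator, and
    downstream analyses: univariate scans, effect-direction concordance,
    MAF/LD-stratified estimates, discovery/validation variance recovery and
    polygenic scores with interaction terms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
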