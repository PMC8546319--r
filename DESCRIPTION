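Package: prodpcss
Title: Covariate-Adjusted Regression for Products of Phenotypes from
    Pre-Computed Summary Statistics
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs covariate-adjusted multiple linear regression
    models for products of phenotypes (ratios via reciprocals, and logical
    AND/OR combinations of binary phenotypes) using only pre-computed
    summary statistics (PCSS): per-variable means, a joint
    variance-covariance matrix, the sample size, and marginal-distribution
    assumptions for predictors. No individual participant data is needed.
    Product means, variances, and predictor covariances are approximated
    through conditional-moment arguments (linear conditional means,
    homoscedastic conditional variances, partial correlations), with
    recursion and permutation-median aggregation for products of three or
    more phenotypes, and Bernoulli-specific estimators for binary
    phenotypes. Missing summary statistics can be derived from GWAS
    repository quantities (Hardy-Weinberg genotype moments from the minor
    allele frequency, covariances from single-marker slopes, phenotype
    correlations from Z-statistic correlations at null markers). A
    synthetic-data module generates individual-level data with the assumed
    statistical structure, computes exact summary statistics from it, and
    runs Type-I-error and IPD-comparison simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
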