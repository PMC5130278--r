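Package: longprs
Title: Polygenic Risk Scores for Longitudinal Alcohol Consumption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derivation and evaluation of weighted polygenic risk scores
    (PGRS) for repeated measures of alcohol consumption. Provides a
    synthetic cohort generator emulating a longitudinal mother/offspring
    study design with a candidate SNP panel and zero-inflated weekly
    alcohol units; per-SNP association via linear mixed models with a
    person random intercept and via cross-sectional log-linear regression;
    p-value-threshold score construction with repeated 80/20
    cross-validation; a truncated-normal forward model of expected score
    accuracy with maximum-likelihood estimation of the variance explained;
    pleiotropy screening of instruments against candidate confounders;
    and Mendelian-randomisation design calculations (power and required
    sample size) for binary and continuous outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
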