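Package: ssripgx
Title: CYP2C19 Metaboliser Status and SSRI Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacogenomic analysis of selective serotonin
    reuptake inhibitor (SSRI) response by CYP2C19 metaboliser status.
    Translates genotypes at the three tier-1 CYP2C19 variants (rs12248560,
    rs4244285, rs4986893) into star-allele diplotypes and CPIC metaboliser
    phenotypes; simulates realistic depression-cohort data (genotypes,
    demographics, overlapping SSRI exposure, ordinal efficacy and binary
    side-effect outcomes with participant-level random intercepts); fits
    proportional-odds and logistic association models, including
    random-intercept variants via adaptive Gauss-Hermite quadrature for
    pooled repeated-measures analyses; and estimates statistical power for
    ordinal efficacy outcomes by simulation.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    statmod,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    lme4,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
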