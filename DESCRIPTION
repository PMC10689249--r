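Package: minppv
Title: Genetic Validation of Biobank Phenotype Definitions via
    Effect-Size Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Validates candidate biobank phenotype definitions against a
    specialist-diagnosed reference cohort using GWAS summary statistics.
    An inverse-variance-weighted regression of candidate effect sizes on
    reference effect sizes at established risk loci yields a slope that
    lower-bounds the positive predictive value (minPPV) of the candidate
    case definition. Includes allele harmonization of summary statistics,
    simulation of case-control cohorts with a known misclassification
    rate to validate slope recovery, an attenuation-aware power
    calculator for common weak genetic effects, and k-of-n composite
    phenotype rules over per-participant data-source indicators.
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
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
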