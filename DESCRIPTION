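Package: ptvsurv
Title: Protein-Truncating Variant Burden Survival and Phenome-Wide Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for exome-wide protein-truncating
    variant (PTV) burden survival analysis in biobank-scale cohorts.
    Qualifies rare high-confidence PTVs from variant and annotation tables,
    constructs censored proband and parental-lifespan proxy survival
    phenotypes with full exclusion accounting, collapses variants into
    gene, gene-set and exome-wide burden scores, fits Cox proportional
    hazards models by damped Newton maximisation of the Efron or Breslow
    partial likelihood with Schoenfeld diagnostics and genomic-inflation
    estimates, runs phenome-wide association scans with Firth
    penalized-likelihood refits for separated binary traits, classifies
    somatic versus germline PTVs from variant allele fractions and
    read-pair phasing evidence, and generates seeded synthetic cohorts
    with recorded ground truth for calibration and recovery testing.
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
    stringr,
    tibble,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
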