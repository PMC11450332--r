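Package: compositemr
Title: One-Sample Mendelian Randomization with Composite-SNP Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomization of binary
    exposures and outcomes, centered on expanding the instrumental-variable
    candidate pool by pairing candidate-gene SNPs into "composite" variants
    whose summed minor-allele dosages are recoded to a pseudo-genotype.
    Includes a synthetic cohort generator with known ground truth, PLINK
    bed/bim/fam input/output with quality-control filters, instrument
    screening against the three instrumental-variable assumptions with
    F-statistic and linkage-disequilibrium criteria, inverse-variance
    weighted, penalized inverse-variance weighted, weighted-median and
    MR-Egger estimators, E-value sensitivity summaries, and left-truncated
    Kaplan-Meier descriptive output.
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
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
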