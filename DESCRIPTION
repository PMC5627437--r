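Package: favsig
Title: Favorability-Score Expression Signatures of Chemotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Derives combined gene-expression signatures of response to
    antimetabolite chemotherapies from tumor cohorts and cancer cell-line
    panels. Provides a genome-wide univariate proportional-hazards screen
    against progression-free survival with clinical-confounder filtering,
    discretization of expression into favorability scores, k-means
    stratification of samples into response subgroups with cross-validated
    survival comparison, a single-gene optimal-cutpoint baseline, Kendall-tau
    screening of expression against drug IC-50 in cell lines, phenotype
    correlates of sensitivity with a volume-corrected growth-rate adjustment,
    Fisher's-exact gene-set enrichment, and synthetic-cohort generators with
    known planted structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
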