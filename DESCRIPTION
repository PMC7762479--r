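Package: methylSexAging
Title: Sex-Specific Age-Related Remodeling of Whole-Blood DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the four-axis analysis of sex-specific
    epigenetic aging in whole-blood methylation array data: discovery of sex-
    and age-associated differentially methylated positions (saDMPs) by
    concordance-filtered sample-size-weighted meta-analysis, discovery of
    sex-specific age-associated variably methylated positions (saVMPs) by
    per-sex Breusch-Pagan heteroscedasticity testing, per-subject epimutation
    burden from interquartile-range outlier bounds, and normalized Shannon
    entropy of the methylome after cell-composition adjustment. Includes a
    multi-cohort synthetic methylome generator with ground truth so that every
    stage is testable without cohort downloads, plus Fisher-exact enrichment
    of probe catalogs in genomic-region, imprinted-region and hormone-gene
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
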