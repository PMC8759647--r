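Package: geiplast
Title: Gene-by-Environment Analysis of Yeast Invasive Growth from Plate-Washing Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies yeast invasive growth from plate-washing assay images
    and turns the results into gene-by-environment interaction (GEI) analyses.
    Provides image preprocessing (rolling-ball style background removal,
    batch-wide contrast rescaling), colony segmentation, invasion indices
    normalized to colony area, wild-type-relative GEI matrices with heat-map
    rendering, transect plot profiles for microenvironment invasion patterns,
    particle-based cell adhesion statistics, a multi-threshold regulator
    ranking scheme, group-comparison statistics (one-way ANOVA with Dunnett
    and Tukey adjustment), 2^-delta-Ct qPCR expression, rule-based classifiers
    for conditional role reversals, double-mutant additivity/redundancy and
    environment sensing, and a seeded synthetic-data generator with planted
    pathway-contribution ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    stats,
    multcomp,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
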