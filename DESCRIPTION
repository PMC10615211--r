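Package: granulefit
Title: Deconvolution and Phenotyping of Bimodal Starch Granule Size
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative phenotyping of starch granules in
    Triticeae endosperm from Coulter-counter particle size data. Converts
    binned or per-particle diameter data into number- and volume-weighted
    size distributions, deconvolves bimodal volume distributions into A-
    and B-type log-normal components by seeded multi-start least squares,
    and derives granule statistics (B-type granule volume percentage, mean
    component diameters, percentage of granules below a diameter
    threshold, granules per milligram fresh weight). Also implements
    affinity-pulldown enrichment filtering of replicated protein
    quantification tables (fold-change and Welch t-test with
    Benjamini-Hochberg adjustment), iodine-colorimetry apparent-amylose
    calibration, one-way ANOVA with Tukey HSD compact letter displays, and
    seeded synthetic-data generators for every input type.
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
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
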