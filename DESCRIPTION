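Package: senescape
Title: Quantifying Cellular Senescence Burden in Single-Nucleus and Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify cellular senescence burden in brain tissue from
    single-nucleus RNA-seq and imaging mass cytometry (IMC) single-cell tables.
    Scores nuclei for senescence gene-set activity by rank-based AUC
    (AUCell-style recovery curves) and bin-matched control module scores, calls
    senescent nuclei by a robust median + k*MAD outlier threshold, contrasts
    senescent proportions between diagnosis groups with Wilcoxon rank-sum tests
    and rank-biserial effect sizes, regresses sub-population fractions against
    beta-amyloid load, fits a linear-plateau model of senescence score versus
    donor age, pools per-dataset case-control differences with a
    DerSimonian-Laird random-effects meta-analysis, and classifies peri-plaque
    microglia by spatial proximity to amyloid plaque objects. Includes seeded
    synthetic-data generators with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
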