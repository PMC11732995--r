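Package: metgxe
Title: Multi-Environment Trial Analysis of Yield Stability and Breeding Progress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for plot-level multi-environment trial (MET)
    data from cultivar panels grown across year x location x management
    combinations ("growing conditions"). Provides quality control (range
    recoding and per-condition four-sigma outlier exclusion), a total fungal
    infection score, per-condition best linear unbiased estimates (BLUEs) of
    cultivar means with row and column random effects, trait consistency
    across growing conditions via standardized major axis regression with
    ANOVA and Fisher LSD letter displays, breeding-progress estimation and
    its multi-linear decomposition, nine classical yield-stability indices
    (Finlay-Wilkinson, Eberhart-Russell, Pinthus, Wricke, Shukla, Hanson,
    Lin-Binns, Nassar-Huehn, environmental variance) with LMG relative
    importance, comparison of trait-trait correlation structure between
    field and crop-model tables, and a seeded synthetic MET generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
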