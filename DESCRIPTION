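Package: bearmarks
Title: Behavioral Analysis of Brown Bear Marking at Rubbing Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing camera-trap records of brown bear (Ursus arctos)
    marking behavior at rubbing trees: ethogram-coded event logs with
    independence filtering, sex/age by behavior tabulations, first-order Markov
    analysis of behavioral sequences with transition pruning and diagram export,
    solar-anchored temporal analysis (diel periods, sun-relative time, monthly
    relative independent capture rates, actogram tables), and the inferential
    layer used in rubbing-tree studies (exposure-corrected chi-square
    goodness-of-fit tests with exact binomial Bonferroni post hocs, binomial
    GLMs of debarking probability with AICc model comparison, and one-way ANOVA
    with Tukey post hoc tests on behavior durations). A synthetic visit
    generator reproduces the statistical structure the analyses assume, so the
    whole pipeline can be exercised without footage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    geosphere,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
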