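Package: cervicomp
Title: Compositional Analysis of Cervicovaginal Microbiome Profiles Across
    Cervical Disease States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for genus-level cervicovaginal
    microbiome cohorts spanning Normal, LSIL, HSIL and invasive cervical
    carcinoma (CCU): alpha diversity with nonparametric group comparisons
    and Cliff's delta, Aitchison (CLR-Euclidean) beta diversity with PCoA,
    PERMANOVA, PERMDISP and a single-factor host screen, a bias-corrected
    compositional differential-abundance estimator in the ANCOM-BC family,
    Lactobacillus-to-anaerobe and data-driven composite log-ratio indices
    with ROC evaluation, per-group co-occurrence network inference, and a
    seeded zero-inflated Dirichlet-multinomial cohort simulator emulating
    published group profiles so every stage is testable without raw data.
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
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    vegan,
    yaml
Config/testthat/edition: 3
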