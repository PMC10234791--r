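Package: facecue
Title: Facial Shape Dimorphism Scoring and Paternal-Involvement Cue Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for testing whether facial shape
    sexual dimorphism is used as (and is an accurate) cue to paternal
    involvement. Reads 2D facial landmark files (Webmorph TEM, TPS), performs
    Generalized Procrustes Analysis and vector-method sexual-dimorphism
    scoring against male and female reference faces, aggregates inter-rater
    trait judgements with seriousness-based exclusions, scores nurturant
    fathering and father-involvement self-report scales, and fits winsorised
    standardized regressions with default Zellner-Siow (JZS) Bayes factors for
    each focal effect, plus a priori noncentral-F power analysis. A
    synthetic-study generator with known ground truth supports calibration and
    parameter-recovery experiments end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
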