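Package: familycode
Title: Family-Level Modeling of Transcription Factor Base Preference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps variation in transcription-factor protein sequence to
    variation in DNA base preference within a structural family (bHLH,
    homeodomain) using a reference-free tetrahedral embedding of
    position-specific affinity matrix (PSAM) columns. Provides MANOVA
    association mapping between residue positions and DNA positions,
    per-DNA-position SVD regression with ANOVA-ranked forward feature
    selection, prediction of binding free-energy (ddG/RT) models for
    unseen family members, and prediction of the binding free-energy
    shifts (dddG/RT) caused by missense mutations in the DNA-binding
    domain. Includes closest-paralog and similarity-regression baselines,
    leave-one-out cross-validation with sequence-distance thresholds, the
    evaluation statistics used to benchmark them, and a synthetic family
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
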