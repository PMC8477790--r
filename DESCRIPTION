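Package: tmepre
Title: Two-Component Tumor Microenvironment Scoring for Anti-PD1 Response
    Prediction in Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and applies TMEPRE, a colorectal-cancer gene-expression
    model with two nearest-centroid components: an infiltration score for
    CD8+ T-cell abundance in the tumor microenvironment and an exhaustion
    score for whether infiltrating CD8+ T cells are terminally exhausted.
    Signatures are selected by stability selection (repeated cross-validated
    t-test ranking) from marker-defined contrasts between microsatellite
    instable and stable tumors. Includes decision rules for training and
    validation cohorts, a CD8-restricted read-out for purified T-cell data,
    survival evaluation (log-rank, Cox proportional hazards, Stouffer
    combination), a synthetic-cohort simulator with planted ground truth,
    and a command-line interface.
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
    jsonlite,
    optparse,
    rlang,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
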