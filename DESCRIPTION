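Package: gsdiv
Title: Multisystem Involvement Assessment and Phenotype Scoring for
    Glycogen Storage Disease Type IV
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rule-based phenotypic characterization of youth-onset
    glycogen storage disease type IV (GSD IV) from structured per-patient
    clinical records. Classifies hepatic, neuromuscular, and cardiac
    involvement as present, absent, or unknown under explicit-normal
    semantics; assigns four-point neuromuscular (N0-N3) and hepatic (H0-H3)
    severity scores built on onset timing, survival, liver transplant, and
    severe hepatic features; maps two-part (N, H) scores onto the established
    clinical subtypes; and aggregates cohorts into score matrices, tri-system
    Venn distributions, involvement prevalence, and death-timing summaries.
    Includes a deterministic synthetic-cohort generator that realizes
    requested score-cell distributions exactly, with configurable
    missingness, for validation and testing.
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
    stringr,
    tibble,
    tidyr,
    vctrs,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
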