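Package: faersmine
Title: Signal Mining for FAERS-Style Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for pharmacovigilance analysis of FAERS-style
    quarterly spontaneous-report tables (DEMO, DRUG, REAC, THER): ingestion of
    the '$'-delimited ASCII dialect with per-row reject capture, CASEID-based
    deduplication, primary-suspect cohort construction by drug-synonym
    matching, clinical-characteristics summaries, reporting odds ratio (ROR)
    disproportionality analysis at MedDRA PT and SOC level with the
    ROR025 > 1 and N >= 2 signal criterion, expectedness classification
    against drug-label term lists, time-to-onset characterisation (Weibull
    shape-parameter failure profiles and Kaplan-Meier cumulative incidence),
    reporter-type subgroup comparison, and a synthetic-data generator with a
    ground-truth manifest so every stage is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
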