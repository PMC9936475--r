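Package: ehrcurate
Title: Data Quality Curation and Cohort Construction for Multi-Site EHR
    Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for screening, cleaning and curating multi-site
    electronic health record (EHR) extracts in an OMOP-like dialect ahead
    of inpatient drug-effectiveness studies: per-site completeness and
    temporal-missingness profiling with exclusion rules, hospital-stay
    (macrovisit) construction and cohort selection, drug-era
    reconstruction from noisy exposure rows, EHR-continuity
    (prior-history) profiling with standardized mean differences, and
    operationalized in-hospital mortality and acute inpatient event
    outcomes.  Includes a synthetic multi-site EHR generator that plants
    the documented data pathologies with known ground truth, and a
    reproducible end-to-end pipeline that emits audit-ready CSV artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    arrow,
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
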