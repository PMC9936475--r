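# The OMOP-lite dialect: table and column definitions shared by the readers,
# writers, validator and synthetic generator.  A machine-readable copy ships
# in inst/extdata/ehr_dialect_schema.json.

ehr_tables <- function() names(ehr_schema())

ehr_schema <- function() {
  list(
    person = list(
      cols = c(
        person_id = "character", site_id = "character",
        birth_year = "integer", sex = "character", race = "character",
        ethnicity = "character"
      )
    ),
    visit_occurrence = list(
      cols = c(
        visit_id = "character", person_id = "character", site_id = "character",
        visit_kind = "character", start_date = "date", end_date = "date",
        discharge_disposition = "character"
      )
    ),
    drug_exposure = list(
      cols = c(
        person_id = "character", site_id = "character", concept_id = "integer",
        start_date = "date", end_date = "date", drug_type_label = "character"
      )
    ),
    measurement = list(
      cols = c(
        person_id = "character", site_id = "character", variable = "character",
        value = "double", date = "date"
      )
    ),
    condition_occurrence = list(
      cols = c(
        person_id = "character", site_id = "character", concept_id = "integer",
        date = "date"
      )
    ),
    death = list(
      cols = c(
        person_id = "character", site_id = "character", death_date = "date"
      )
    ),
    concept = list(
      cols = c(
        concept_id = "integer", concept_name = "character", level = "character"
      )
    ),
    concept_ancestor = list(
      cols = c(ancestor_id = "integer", descendant_id = "integer")
    ),
    site = list(
      cols = c(
        site_id = "character", source_cdm = "character",
        max_date_shift_days = "integer"
      )
    )
  )
}

visit_kinds <- function() c("inpatient", "emergency", "outpatient", "other")
concept_levels <- function() {
  c("ingredient", "clinical_drug", "branded_drug", "other")
}

#' Key vital-sign variables used for site fitness screening
#'
#' The default set of vital signs whose per-site capture drives the
#' completeness heatmap, hierarchical site clustering, and the 70%
#' missingness exclusion rule.
#'
#' @return Character vector of variable names in the dialect.
#' @export
key_vitals <- function() {
  c("spo2", "respiration_rate", "body_temperature", "heart_rate", "bmi")
}

# catalogue of measurement variables: default per-site capture probability
# (per-patient probability of having at least one value during the stay) and
# a value model used by the generator.  Capture defaults follow the observed
# non-missing fractions of a hospitalized COVID-19 population; values are
# log-normal or normal around the published medians/IQRs.
measurement_catalog <- function() {
  tribble(
    ~variable,          ~capture, ~dist,     ~p1,        ~p2,   ~digits,
    "bmi",              0.762,    "lnorm",   log(29),    0.25,  1,
    "creatinine",       0.428,    "lnorm",   log(0.94),  0.48,  2,
    "bilirubin",        0.194,    "lnorm",   log(0.50),  0.47,  2,
    "pao2",             0.011,    "norm",    79,         14,    0,
    "fio2",             0.024,    "norm",    0.69,       0.23,  2,
    "body_temperature", 0.876,    "norm",    36.8,       0.25,  1,
    "wbc",              0.346,    "lnorm",   log(7.8),   0.48,  1,
    "ferritin",         0.018,    "lnorm",   log(555),   1.05,  0,
    "crp",              0.032,    "lnorm",   log(52),    1.07,  0,
    "il6",              0.003,    "lnorm",   log(34.5),  0.05,  1,
    "spo2",             0.898,    "norm",    95,         1.8,   1,
    "respiration_rate", 0.898,    "norm",    19.5,       2.2,   1,
    "heart_rate",       0.910,    "norm",    85,         15,    0
  )
}

#' Measurement variables known to the dialect
#'
#' @return Character vector of all measurement variable names.
#' @export
measurement_variables <- function() measurement_catalog()$variable

# toy vocabulary used by the synthetic generator --------------------------

sim_concepts <- function() {
  tribble(
    ~concept_id, ~concept_name,                           ~level,
    1001L, "remdesivir",                                  "ingredient",
    1003L, "remdesivir 100 MG Injection",                 "clinical_drug",
    1004L, "remdesivir Injection",                        "clinical_drug",
    1005L, "20 ML remdesivir 5 MG/ML Injection",          "branded_drug",
    1002L, "dexamethasone",                               "ingredient",
    1006L, "dexamethasone 2 MG Oral Tablet",              "clinical_drug",
    1007L, "dexamethasone 0.5 MG Oral Tablet",            "clinical_drug",
    1008L, "dexamethasone 1 MG/ML Oral Solution",         "branded_drug",
    2001L, "essential hypertension",                      "other",
    2002L, "type 2 diabetes mellitus",                    "other",
    2003L, "coronary artery disease",                     "other",
    2004L, "congestive heart failure",                    "other",
    2005L, "chronic obstructive pulmonary disease",       "other",
    2006L, "cerebrovascular disease",                     "other",
    2007L, "chronic kidney disease",                      "other",
    2008L, "cardiac arrhythmia",                          "other",
    2009L, "tobacco smoking",                             "other",
    2010L, "malignant neoplastic disease",                "other",
    3001L, "invasive mechanical ventilation",             "other",
    3002L, "extracorporeal membrane oxygenation",         "other",
    4001L, "acute myocardial infarction",                 "other",
    5001L, "lisinopril",                                  "ingredient",
    5002L, "losartan",                                    "ingredient",
    5003L, "atorvastatin",                                "ingredient"
  )
}

sim_concept_ancestors <- function() {
  ids <- sim_concepts()$concept_id
  bind_rows(
    tibble(ancestor_id = ids, descendant_id = ids),
    tribble(
      ~ancestor_id, ~descendant_id,
      1001L, 1003L,
      1001L, 1004L,
      1003L, 1005L, # branded drug hangs off the clinical drug, not the root
      1002L, 1006L,
      1002L, 1007L,
      1006L, 1008L
    )
  )
}

#' Default concept sets for the synthetic vocabulary
#'
#' Named concept-id sets matching the toy vocabulary emitted by
#' [simulate_ehr_bundle()]: comorbidities, prior medications, ventilation/ECMO
#' and one acute event (myocardial infarction).  Real studies supply their
#' own sets through the same structure.
#'
#' @return Named list of integer concept-id vectors.
#' @export
default_concept_sets <- function() {
  list(
    hypertension    = 2001L,
    diabetes        = 2002L,
    cad             = 2003L,
    chf             = 2004L,
    copd            = 2005L,
    cerebrovascular = 2006L,
    ckd             = 2007L,
    arrhythmia      = 2008L,
    smoking         = 2009L,
    malignancy      = 2010L,
    acei            = 5001L,
    arb             = 5002L,
    statin          = 5003L,
    ventilation     = c(3001L, 3002L),
    mi              = 4001L
  )
}
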