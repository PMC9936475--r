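#' Configuration for an end-to-end curation run
#'
#' Collects every threshold and input of [run_pipeline()] into one
#' serializable list so a run is reproducible from config + inputs alone.
#'
#' @param bundle An [ehr_bundle()], or a directory path to read one from.
#' @param index_events Tibble `person_id`, `index_date`, or a CSV path.
#' @param out_dir Directory for the emitted artifacts.
#' @param format Bundle file format when `bundle` is a path.
#' @param window,admit_window_days,min_stay_days Cohort rules (see
#'   [select_cohort()]).
#' @param merge_gap_days Macrovisit merge gap.
#' @param era_gap_days Drug-era merge gap.
#' @param ingredient_id Study-drug ingredient concept id.
#' @param thresholds Site exclusion thresholds ([site_thresholds()]).
#' @param vitals Key vitals for screening.
#' @param variables Measurement variables profiled.
#' @param concept_sets Concept sets for covariates/outcomes.
#' @param lookback_floor Extract lookback floor date.
#' @param tolerance_days,horizon_days Mortality rule parameters.
#' @param suppress_below Small-cell suppression threshold for the history
#'   table.
#' @param seed Seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bundle, index_events, out_dir,
                            format = "csv",
                            window = as.Date(c("2020-03-01", "2021-09-01")),
                            admit_window_days = 14,
                            min_stay_days = 2,
                            merge_gap_days = 0,
                            era_gap_days = 0,
                            ingredient_id = 1001L,
                            thresholds = site_thresholds(),
                            vitals = key_vitals(),
                            variables = measurement_variables(),
                            concept_sets = default_concept_sets(),
                            lookback_floor = as.Date("2018-01-01"),
                            tolerance_days = 1,
                            horizon_days = 28,
                            suppress_below = 20,
                            seed = 1L) {
  structure(
    list(
      bundle = bundle, index_events = index_events, out_dir = out_dir,
      format = format, window = window,
      admit_window_days = admit_window_days, min_stay_days = min_stay_days,
      merge_gap_days = merge_gap_days, era_gap_days = era_gap_days,
      ingredient_id = ingredient_id, thresholds = thresholds,
      vitals = vitals, variables = variables, concept_sets = concept_sets,
      lookback_floor = lookback_floor, tolerance_days = tolerance_days,
      horizon_days = horizon_days, suppress_below = suppress_below,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full curation pipeline
#'
#' Orchestrates every stage — validation, macrovisits, cohort selection and
#' attrition, site completeness / temporal missingness / clustering /
#' exclusion rules, drug-era reconstruction with duration and claim audits,
#' continuity profiling with the stratified history table and SMDs
#' (no-history vs any-history), and the mortality / disposition outcome
#' audits — and writes each result as a plain CSV into `out_dir` together
#' with a run log recording every threshold used.  Artifacts are plain CSV
#' for auditability, so a rerun under the same config and inputs is
#' byte-identical; figures are left to the `plot_*` functions.  A stage
#' failure propagates as an error with earlier artifacts preserved on disk.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the in-memory stage results plus
#'   `paths` (the artifact files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(x, p, na = "", progress = FALSE)
    paths[[name]] <<- p
    x
  }

  bundle <- config$bundle
  if (is.character(bundle)) bundle <- read_bundle(bundle, config$format)
  idx <- config$index_events
  if (is.character(idx)) {
    idx <- readr::read_csv(idx, col_types = readr::cols(
      person_id = readr::col_character(),
      index_date = readr::col_date()
    ), progress = FALSE)
  }

  emit(validate_bundle(bundle), "validation")

  mv <- build_macrovisits(bundle$visit_occurrence, config$merge_gap_days)
  emit(mv |> mutate(visit_ids = map_chr(visit_ids, paste, collapse = ";")),
       "macrovisits")

  cohort <- select_cohort(
    bundle, mv, idx,
    window = config$window, admit_window_days = config$admit_window_days,
    min_stay_days = config$min_stay_days
  )
  emit(cohort, "cohort")
  emit(attrition(cohort), "attrition")
  if (!any(cohort$included)) abort("no patients pass the inclusion rules")

  comp <- emit(completeness_matrix(bundle, cohort, config$variables),
               "completeness")
  temp <- emit(temporal_missingness(bundle, cohort, config$variables),
               "temporal_missingness")
  clusters <- cluster_sites(
    comp |> filter(variable %in% config$vitals)
  )
  excl <- emit(
    apply_exclusion_rules(comp, temp, bundle$site, config$thresholds,
                          config$vitals, clusters = clusters),
    "site_exclusions"
  )
  emit(patient_missingness_table(bundle, cohort, config$variables),
       "patient_missingness")

  descendants <- descendants_of_ingredient(
    bundle$concept, bundle$concept_ancestor, config$ingredient_id
  )
  emit(concept_distribution(bundle$drug_exposure, bundle$concept, descendants),
       "concept_distribution")
  eras <- build_drug_eras(
    bundle$drug_exposure |> filter(concept_id %in% descendants),
    gap_days = config$era_gap_days, ingredient_id = config$ingredient_id
  )
  emit(eras$eras, "eras")
  emit(eras$log, "era_cleaning_log")
  emit(duration_distribution(eras, cohort, bundle$death), "duration_histogram")
  emit(claim_inferred_breakdown(eras), "claim_breakdown")

  cont <- emit(
    months_prior_history(bundle$visit_occurrence, cohort,
                         config$lookback_floor),
    "continuity"
  )
  covs <- baseline_covariates(bundle, cohort, config$concept_sets)
  joined <- covs |>
    inner_join(cont |> select(person_id, history_group), by = "person_id")
  cov_vars <- setdiff(
    names(covs),
    c("person_id", "site_id", "age_at_index")
  )
  emit(
    history_table(joined, "history_group",
                  c("age_at_index", cov_vars),
                  suppress_below = config$suppress_below),
    "history_table"
  )
  smd_data <- joined |>
    mutate(any_history = ifelse(history_group == "none",
                                "no_history", "any_history"))
  emit(smd_table(smd_data, "any_history"), "smd")
  emit(no_history_heatmap(cohort, cont), "no_history_heatmap")

  mort <- emit(
    classify_mortality(cohort, bundle$death, bundle$visit_occurrence,
                       config$tolerance_days, config$horizon_days),
    "mortality_calls"
  )
  emit(death_delta_distribution(mort), "death_delta_histogram")
  disp <- disposition_audit(bundle$visit_occurrence)
  emit(disp$top, "disposition_top")
  emit(disp$by_site, "disposition_by_site")

  log_lines <- c(
    "ehrcurate pipeline run log",
    paste0("seed: ", config$seed),
    paste0("window: ", paste(config$window, collapse = " .. ")),
    paste0("admit_window_days: ", config$admit_window_days),
    paste0("min_stay_days: ", config$min_stay_days),
    paste0("merge_gap_days: ", config$merge_gap_days),
    paste0("era_gap_days: ", config$era_gap_days),
    paste0("ingredient_id: ", config$ingredient_id),
    paste0("vitals_missing_max: ", config$thresholds$vitals_missing_max),
    paste0("sd_mult: ", config$thresholds$sd_mult),
    paste0("max_shift_days: ", config$thresholds$max_shift_days),
    paste0("lookback_floor: ", config$lookback_floor),
    paste0("tolerance_days: ", config$tolerance_days),
    paste0("horizon_days: ", config$horizon_days),
    paste0("suppress_below: ", config$suppress_below),
    paste0("n_indexed: ", nrow(cohort)),
    paste0("n_included: ", sum(cohort$included)),
    paste0("n_sites_excluded: ", sum(excl$excluded)),
    paste0("n_eras: ", nrow(eras$eras))
  )
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  paths[["run_log"]] <- file.path(out_dir, "run_log.txt")

  invisible(list(
    bundle = bundle, macrovisits = mv, cohort = cohort,
    completeness = comp, temporal = temp, clusters = clusters,
    site_exclusions = excl, eras = eras, continuity = cont,
    covariates = covs, mortality = mort, disposition = disp,
    paths = paths
  ))
}
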