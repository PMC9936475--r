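#' Merge raw hospital visits into macrovisits
#'
#' A macrovisit is a maximal set of inpatient and emergency-department visit
#' rows for one person that overlap or sit within `merge_gap_days` empty days
#' of each other, merged into a single continuous care episode.  Intervals
#' are closed on both ends; an absent end date is treated as end = start, and
#' a reversed visit interval contributes its start day only.  The union of
#' covered days is preserved and construction is idempotent.
#'
#' @param visits Visit rows (`visit_id`, `person_id`, `site_id`,
#'   `visit_kind`, `start_date`, `end_date`); kinds other than inpatient and
#'   emergency are ignored.
#' @param merge_gap_days Maximum number of empty days between two visits that
#'   still merges them.  The default 0 merges overlapping or abutting visits
#'   only; the published merge heuristic of the source enclave is not public,
#'   so this conservative rule is the documented stand-in.
#' @return Tibble with one row per macrovisit: `macrovisit_id`, `person_id`,
#'   `site_id`, `start_date`, `end_date`, `length_days`
#'   (= end - start + 1), `n_visits` and a `visit_ids` list-column.
#' @export
build_macrovisits <- function(visits, merge_gap_days = 0) {
  visits |>
    filter(visit_kind %in% c("inpatient", "emergency")) |>
    mutate(
      end_date = coalesce(end_date, start_date),
      end_date = pmax(end_date, start_date)
    ) |>
    consolidate_intervals(merge_gap_days) |>
    group_by(person_id, .data$.grp) |>
    summarise(
      site_id = first(site_id),
      start_date = min(start_date),
      end_date = max(end_date),
      visit_ids = list(visit_id),
      n_visits = n(),
      .groups = "drop"
    ) |>
    mutate(
      macrovisit_id = sprintf("%s-M%d", person_id, .data$.grp),
      length_days = as.integer(end_date - start_date) + 1L
    ) |>
    select(macrovisit_id, person_id, site_id, start_date, end_date,
           length_days, n_visits, visit_ids)
}

#' Select the hospitalized study cohort
#'
#' Applies the study inclusion rules to one index event per person: adults
#' (age >= 18 at index, computed as index year minus birth year), non-missing
#' age and sex, an index date on or after `min_index_date` (earlier positive
#' tests are implausible), a first qualifying macrovisit starting within
#' `admit_window_days` of the index date and inside the study `window`, and a
#' stay of at least `min_stay_days` days.  Every person with an index event
#' gets a row; each rule's outcome is recorded in a `flag_*` column and
#' `included` is their conjunction, so exclusions are auditable (see
#' [attrition()]).
#'
#' @param bundle An [ehr_bundle()].
#' @param macrovisits Output of [build_macrovisits()].
#' @param index_events Tibble `person_id`, `index_date` (first qualifying
#'   COVID-19 event; any per-person date source is accepted).
#' @param window Two dates bounding qualifying hospital admissions.
#' @param admit_window_days Maximum days between index date and macrovisit
#'   start (the source study does not state its index-to-admission window;
#'   14 days is the documented default).
#' @param min_stay_days Minimum macrovisit length in days.
#' @param min_age Minimum age at index.
#' @param min_index_date Earliest plausible index date.
#' @return Tibble with one row per indexed person: identifiers, the selected
#'   macrovisit (`macrovisit_id`, `admission_date`, `discharge_date`,
#'   `length_days`), `age_at_index`, `sex`, the `flag_*` columns and
#'   `included`.
#' @export
select_cohort <- function(bundle, macrovisits, index_events,
                          window = as.Date(c("2020-03-01", "2021-09-01")),
                          admit_window_days = 14,
                          min_stay_days = 2,
                          min_age = 18,
                          min_index_date = as.Date("2020-01-01")) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  idx <- index_events |>
    mutate(index_date = as.Date(index_date)) |>
    distinct(person_id, .keep_all = TRUE) |>
    left_join(bundle$person, by = "person_id")

  candidates <- idx |>
    select(person_id, index_date) |>
    inner_join(
      macrovisits |>
        select(person_id, macrovisit_id, admission_date = start_date,
               discharge_date = end_date, length_days),
      by = "person_id"
    ) |>
    filter(
      admission_date >= index_date - admit_window_days,
      admission_date <= index_date + admit_window_days,
      admission_date >= window[1],
      admission_date <= window[2]
    ) |>
    arrange(person_id, admission_date) |>
    distinct(person_id, .keep_all = TRUE) # first qualifying hospitalization

  idx |>
    left_join(select(candidates, -index_date), by = "person_id") |>
    mutate(
      age_at_index = date_year(index_date) - birth_year,
      flag_demographics = !is.na(birth_year) & !is.na(sex),
      flag_adult = !is.na(age_at_index) & age_at_index >= min_age,
      flag_index_plausible = index_date >= min_index_date,
      flag_hospitalized = !is.na(macrovisit_id),
      flag_min_stay = !is.na(length_days) & length_days >= min_stay_days,
      included = flag_demographics & flag_adult & flag_index_plausible &
        flag_hospitalized & flag_min_stay
    ) |>
    select(person_id, site_id, index_date, macrovisit_id, admission_date,
           discharge_date, length_days, age_at_index, sex,
           starts_with("flag_"), included)
}

#' Attrition table for a cohort selection
#'
#' Applies the inclusion rules sequentially, in their documented order, and
#' counts how many candidates each rule removes; cohort size is monotone
#' non-increasing down the table.
#'
#' @param cohort Output of [select_cohort()].
#' @return Tibble `rule`, `n_excluded`, `n_remaining`, starting from the
#'   `indexed` row (all persons with an index event).
#' @export
attrition <- function(cohort) {
  rules <- c("flag_demographics", "flag_adult", "flag_index_plausible",
             "flag_hospitalized", "flag_min_stay")
  remaining <- rep(TRUE, nrow(cohort))
  out <- tibble(rule = "indexed", n_excluded = 0L,
                n_remaining = nrow(cohort))
  for (r in rules) {
    keep <- remaining & cohort[[r]]
    out <- add_row(out,
      rule = sub("^flag_", "", r),
      n_excluded = sum(remaining) - sum(keep),
      n_remaining = sum(keep)
    )
    remaining <- keep
  }
  out
}
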