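#' All descendants of an ingredient in the concept hierarchy
#'
#' Transitive closure of the ancestor relation starting from one
#' ingredient-level concept, always including the ingredient itself.  The
#' ancestor table is treated as an edge list (it need not be pre-closed).
#'
#' @param concepts Concept table (`concept_id`, `concept_name`, `level`).
#' @param ancestors Ancestor table (`ancestor_id`, `descendant_id`).
#' @param ingredient_id Concept id of the ingredient.
#' @return Sorted integer vector of descendant concept ids (including the
#'   ingredient).
#' @export
descendants_of_ingredient <- function(concepts, ancestors, ingredient_id) {
  lev <- concepts$level[match(ingredient_id, concepts$concept_id)]
  if (is.na(lev)) abort("ingredient_id not found in the concept table")
  if (lev != "ingredient") {
    abort(sprintf("concept %s is not at ingredient level", ingredient_id))
  }
  edges <- ancestors |> filter(ancestor_id != descendant_id)
  out <- as.integer(ingredient_id)
  repeat {
    nxt <- edges$descendant_id[edges$ancestor_id %in% out]
    nxt <- setdiff(nxt, out)
    if (length(nxt) == 0) break
    out <- c(out, nxt)
  }
  sort(as.integer(out))
}

#' Distribution of drug concept names within a descendant set
#'
#' Counts raw exposure rows per concept name for one ingredient's descendant
#' set, in descending order — the coding-level mix (ingredient vs clinical
#' vs branded drug) that determines whether dose and route are recoverable.
#'
#' @param drug_rows Drug exposure rows.
#' @param concepts Concept table.
#' @param descendant_set Concept ids, e.g. from
#'   [descendants_of_ingredient()].
#' @return Tibble `concept_name`, `n`, `percent` (percents sum to 100 up to
#'   rounding); zero rows for an empty row set.
#' @export
concept_distribution <- function(drug_rows, concepts, descendant_set) {
  drug_rows |>
    filter(concept_id %in% descendant_set) |>
    inner_join(concepts |> select(concept_id, concept_name),
               by = "concept_id") |>
    count(concept_name, sort = TRUE) |>
    mutate(percent = 100 * n / sum(n))
}

#' Reconstruct drug eras from raw exposure rows
#'
#' Builds consolidated continuous exposure intervals ("drug eras") for one
#' ingredient's rows with the inpatient-appropriate cleaning sequence:
#' \enumerate{
#'   \item discard rows whose end date precedes their start date (logged);
#'   \item treat absent end dates as single-day exposures (end = start);
#'   \item deduplicate identical (person, start, end) rows;
#'   \item sort by start date;
#'   \item merge intervals that overlap or are separated by at most
#'     `gap_days` empty days.
#' }
#' The default `gap_days = 0` merges contiguous intervals only; the 30-day
#' outpatient persistence window of the derived OMOP era table is available
#' via `gap_days = 30` but is inappropriate for short-term inpatient care.
#' Duplicate same-start pairs of one bounded one-day interval and one
#' unbounded interval collapse naturally under rules 2-3.  Total covered
#' days are conserved: the sum of era `exposure_days` equals the size of the
#' union of the retained rows' day sets.
#'
#' @param drug_rows Rows for one (person set, ingredient descendant set):
#'   `person_id`, `start_date`, `end_date`; `site_id`, `concept_id` and
#'   `drug_type_label` are carried through when present.
#' @param gap_days Maximum empty-day gap merged into one era.
#' @param ingredient_id Optional id stamped on the output eras.
#' @return Object of class `drug_eras`: list with
#'   \describe{
#'     \item{eras}{`era_id`, `person_id`, `ingredient_id`, `start_date`,
#'       `end_date`, `exposure_days` (= end - start + 1), `n_source_rows`,
#'       `any_claim_inferred`, `site_id`}
#'     \item{rows}{the retained (cleaned, pre-deduplication) rows with their
#'       `era_id`}
#'     \item{log}{cleaning log: counts of discarded reversed rows, open
#'       intervals closed, duplicates removed}
#'   }
#' @export
build_drug_eras <- function(drug_rows, gap_days = 0, ingredient_id = NA_integer_) {
  rows <- drug_rows |>
    mutate(
      site_id = if ("site_id" %in% names(drug_rows)) site_id else NA_character_,
      drug_type_label = if ("drug_type_label" %in% names(drug_rows)) {
        drug_type_label
      } else NA_character_
    )
  reversed <- !is.na(rows$end_date) & rows$end_date < rows$start_date
  open <- is.na(rows$end_date)
  retained <- rows |>
    filter(!reversed) |>
    mutate(end_date = coalesce(end_date, start_date))
  dedup <- retained |> distinct(person_id, start_date, end_date)
  eras <- dedup |>
    consolidate_intervals(gap_days) |>
    group_by(person_id, .data$.grp) |>
    summarise(
      start_date = min(start_date), end_date = max(end_date),
      .groups = "drop"
    ) |>
    mutate(
      era_id = sprintf("%s-E%d", person_id, .data$.grp),
      exposure_days = as.integer(end_date - start_date) + 1L,
      ingredient_id = ingredient_id
    )
  rows_tagged <- retained |>
    left_join(
      eras |>
        select(person_id, era_id, era_start = start_date,
               era_end = end_date),
      by = join_by(person_id, between(start_date, era_start, era_end))
    ) |>
    select(-era_start, -era_end)
  era_meta <- rows_tagged |>
    group_by(era_id) |>
    summarise(
      n_source_rows = n(),
      any_claim_inferred = any(drug_type_label == "Inferred from claim",
                               na.rm = TRUE),
      site_id = first(site_id),
      .groups = "drop"
    )
  eras <- eras |>
    left_join(era_meta, by = "era_id") |>
    select(era_id, person_id, ingredient_id, start_date, end_date,
           exposure_days, n_source_rows, any_claim_inferred, site_id) |>
    arrange(person_id, start_date)
  log <- tibble(
    action = c("discarded_reversed", "open_as_single_day", "duplicates_removed"),
    n = c(sum(reversed), sum(open & !reversed), nrow(retained) - nrow(dedup))
  )
  structure(list(eras = eras, rows = rows_tagged, log = log,
                 gap_days = gap_days),
            class = "drug_eras")
}

#' @export
print.drug_eras <- function(x, ...) {
  cat("<drug_eras>", nrow(x$eras), "eras for",
      n_distinct(x$eras$person_id), "patients (gap_days =", x$gap_days, ")\n")
  print(x$log)
  invisible(x)
}

#' First-era treatment duration distribution
#'
#' Counts patients by the exposure-day length of their first (earliest) drug
#' era.  With `terminal_filter = "drop_if_ends_at_discharge_or_death"`,
#' patients whose first era ends on their macrovisit end date or on their
#' death date are removed, isolating courses whose observed termination is
#' not explained by discharge or death.
#'
#' @param eras A [build_drug_eras()] result or its `eras` tibble.
#' @param cohort Output of [select_cohort()] (for discharge dates).
#' @param deaths The bundle's `death` table (optional, needed for the death
#'   side of the filter).
#' @param terminal_filter `"none"` or
#'   `"drop_if_ends_at_discharge_or_death"`.
#' @return Tibble `duration_days`, `n`, `prop`.
#' @export
duration_distribution <- function(eras, cohort, deaths = NULL,
                                  terminal_filter = c("none", "drop_if_ends_at_discharge_or_death")) {
  terminal_filter <- match.arg(terminal_filter)
  if (inherits(eras, "drug_eras")) eras <- eras$eras
  first_eras <- eras |>
    arrange(person_id, start_date) |>
    distinct(person_id, .keep_all = TRUE) |>
    inner_join(cohort |>
                 filter(included) |>
                 select(person_id, discharge_date),
               by = "person_id")
  if (terminal_filter == "drop_if_ends_at_discharge_or_death") {
    death_dates <- if (is.null(deaths)) {
      tibble(person_id = character(), death_date = as.Date(character()))
    } else {
      deaths |> distinct(person_id, .keep_all = TRUE) |>
        select(person_id, death_date)
    }
    first_eras <- first_eras |>
      left_join(death_dates, by = "person_id") |>
      filter(
        end_date != discharge_date,
        is.na(death_date) | end_date != death_date
      )
  }
  first_eras |>
    count(duration_days = exposure_days) |>
    mutate(prop = n / sum(n))
}

#' Provenance of rows behind single-day eras
#'
#' Among the retained exposure rows that back single-day eras, counts rows by
#' site and drug type label (absent labels count under `"missing"`) — the
#' audit that exposes claim-inferred single-day artifacts and their
#' concentration at particular sites.
#'
#' @param eras A [build_drug_eras()] result.
#' @return Tibble `site_id`, `drug_type_label`, `n`, `share` (of all
#'   single-day-era rows); zero rows when there are no single-day eras.
#' @export
claim_inferred_breakdown <- function(eras) {
  stopifnot(inherits(eras, "drug_eras"))
  single <- eras$eras |> filter(exposure_days == 1L)
  eras$rows |>
    filter(era_id %in% single$era_id) |>
    mutate(drug_type_label = coalesce(drug_type_label, "missing")) |>
    count(site_id, drug_type_label, sort = TRUE) |>
    mutate(share = n / sum(n))
}
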