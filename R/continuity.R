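#' Months of prior EHR history per cohort patient
#'
#' History depth is the number of whole months (default month length
#' 30.4375 days) between a patient's earliest recorded visit of any kind —
#' no older than the lookback floor and strictly before the macrovisit start
#' — and that macrovisit start, capped at `cap` months (the maximum
#' measurable given the floor).  Patients with no prior visit form the
#' `none` group; capped patients form `cap_24plus`; everyone else is
#' `under_24` (a prior visit less than one month back yields months = 0 in
#' that group).
#'
#' @param visits The bundle's `visit_occurrence` table (all kinds).
#' @param cohort Output of [select_cohort()]; only `included` rows are
#'   profiled.
#' @param lookback_floor Earliest calendar date present in the extract.
#' @param month_length Days per month used for the conversion.
#' @param cap Cap in months.
#' @return Tibble `person_id`, `earliest_visit_date` (`NA` for group
#'   `none`), `months_prior_history`, `history_group` (factor
#'   none/under_24/cap_24plus).  Groups partition the cohort.
#' @export
months_prior_history <- function(visits, cohort,
                                 lookback_floor = as.Date("2018-01-01"),
                                 month_length = 30.4375, cap = 24L) {
  pats <- cohort |> filter(included) |> select(person_id, admission_date)
  earliest <- pats |>
    inner_join(visits |> select(person_id, start_date), by = "person_id",
               relationship = "many-to-many") |>
    filter(start_date >= lookback_floor, start_date < admission_date) |>
    group_by(person_id) |>
    summarise(earliest_visit_date = min_date(start_date), .groups = "drop")
  pats |>
    left_join(earliest, by = "person_id") |>
    mutate(
      months_prior_history = ifelse(
        is.na(earliest_visit_date), 0L,
        pmin(floor(as.integer(admission_date - earliest_visit_date) /
                     month_length), cap)
      ),
      history_group = factor(
        case_when(
          is.na(earliest_visit_date) ~ "none",
          months_prior_history >= cap ~ "cap_24plus",
          TRUE ~ "under_24"
        ),
        levels = c("none", "under_24", "cap_24plus")
      )
    ) |>
    select(person_id, earliest_visit_date, months_prior_history, history_group)
}

#' Baseline covariate vector per cohort patient
#'
#' Binary indicators of presence of at least one matching code before the
#' macrovisit start: comorbidities from condition codes (any time before
#' admission, subject to the extract's lookback floor), prior medications
#' from drug codes within `med_lookback_days` of admission.  Visit-level
#' fields: `ventilated_on_admission` (ventilation/ECMO code within the first
#' `vent_window_days` days of the stay) and `in_hospital_mortality` (from
#' [classify_mortality()] with default tolerances).  Demographics are banded
#' the way baseline tables report them; BMI uses the first in-stay value.
#'
#' @param bundle An [ehr_bundle()].
#' @param cohort Output of [select_cohort()].
#' @param concept_sets Named list of concept-id vectors (see
#'   [default_concept_sets()]); names prefixed `acei`, `arb`, `statin` are
#'   treated as medications, `ventilation` drives the ventilation indicator,
#'   all other names become comorbidity indicators.
#' @param med_lookback_days Lookback for medication indicators (default
#'   `Inf`: any time before admission above the floor).
#' @param vent_window_days Length of the on-admission window in days.
#' @return Tibble, one row per included patient: `person_id`, `site_id`,
#'   `age_at_index`, `age_band`, `sex`, `race`, `ethnicity`, `bmi_band`, one
#'   logical column per concept set, `ventilated_on_admission`,
#'   `in_hospital_mortality`.
#' @export
baseline_covariates <- function(bundle, cohort,
                                concept_sets = default_concept_sets(),
                                med_lookback_days = Inf,
                                vent_window_days = 2) {
  pats <- cohort |>
    filter(included) |>
    select(person_id, site_id, admission_date, discharge_date,
           age_at_index, sex)
  demo <- pats |>
    left_join(bundle$person |> select(person_id, race, ethnicity),
              by = "person_id") |>
    mutate(
      age_band = cut(age_at_index, c(17, 49, 59, 69, Inf),
                     labels = c("18-49", "50-59", "60-69", ">=70")),
    )
  bmi <- bundle$measurement |>
    filter(variable == "bmi") |>
    inner_join(pats |> select(person_id, admission_date, discharge_date),
               by = "person_id") |>
    filter(date >= admission_date, date <= discharge_date) |>
    arrange(person_id, date) |>
    distinct(person_id, .keep_all = TRUE) |>
    transmute(person_id, bmi_band = cut(
      value, c(-Inf, 24.999, 29.999, 34.999, 39.999, Inf),
      labels = c("<25", "25-29", "30-34", "35-39", ">=40")
    ))
  demo <- demo |>
    left_join(bmi, by = "person_id") |>
    mutate(bmi_band = forcats_na_level(bmi_band))

  med_sets <- intersect(names(concept_sets), c("acei", "arb", "statin"))
  vent_set <- concept_sets[["ventilation"]]
  como_sets <- setdiff(names(concept_sets), c(med_sets, "ventilation"))

  out <- demo
  for (nm in como_sets) {
    hits <- bundle$condition_occurrence |>
      filter(concept_id %in% concept_sets[[nm]]) |>
      inner_join(pats |> select(person_id, admission_date), by = "person_id") |>
      filter(date < admission_date) |>
      distinct(person_id)
    out[[nm]] <- out$person_id %in% hits$person_id
  }
  for (nm in med_sets) {
    hits <- bundle$drug_exposure |>
      filter(concept_id %in% concept_sets[[nm]]) |>
      inner_join(pats |> select(person_id, admission_date), by = "person_id") |>
      filter(start_date < admission_date,
             start_date >= admission_date - med_lookback_days) |>
      distinct(person_id)
    out[[nm]] <- out$person_id %in% hits$person_id
  }
  if (!is.null(vent_set)) {
    vent <- bundle$condition_occurrence |>
      filter(concept_id %in% vent_set) |>
      inner_join(pats |> select(person_id, admission_date, discharge_date),
                 by = "person_id") |>
      filter(date >= admission_date,
             date <= pmin(admission_date + vent_window_days - 1, discharge_date)) |>
      distinct(person_id)
    out$ventilated_on_admission <- out$person_id %in% vent$person_id
  }
  mort <- classify_mortality(cohort, bundle$death, bundle$visit_occurrence)
  out |>
    left_join(mort |> select(person_id, call), by = "person_id") |>
    mutate(in_hospital_mortality = coalesce(call == "in_hospital", FALSE)) |>
    select(-call, -admission_date, -discharge_date)
}

# add an explicit "Missing" level in place of NA
forcats_na_level <- function(f, level = "Missing") {
  f <- factor(f, levels = c(levels(f), level))
  f[is.na(f)] <- level
  f
}

#' Standardized mean difference between two groups
#'
#' Scale-free between-group difference computed from summary statistics
#' only.  Binary: `(p_a - p_b) / sqrt((p_a (1 - p_a) + p_b (1 - p_b)) / 2)`;
#' continuous: `(m_a - m_b) / sqrt((s_a^2 + s_b^2) / 2)`.  Antisymmetric in
#' the groups, zero for identical groups (including the degenerate case of a
#' zero pooled spread), and independent of group sizes.  By convention
#' `|SMD| < 0.1` is a negligible difference.
#'
#' @param group_a,group_b Binary: the proportion; continuous: `c(mean, sd)`.
#' @param kind `"binary"` or `"continuous"`.
#' @return The SMD (signed scalar).
#' @export
smd <- function(group_a, group_b, kind = c("binary", "continuous")) {
  kind <- match.arg(kind)
  if (kind == "binary") {
    stopifnot(length(group_a) == 1, length(group_b) == 1,
              group_a >= 0, group_a <= 1, group_b >= 0, group_b <= 1)
    num <- group_a - group_b
    den <- sqrt((group_a * (1 - group_a) + group_b * (1 - group_b)) / 2)
  } else {
    stopifnot(length(group_a) == 2, length(group_b) == 2)
    num <- group_a[[1]] - group_b[[1]]
    den <- sqrt((group_a[[2]]^2 + group_b[[2]]^2) / 2)
  }
  if (den == 0) {
    return(if (num == 0) 0 else sign(num) * Inf)
  }
  num / den
}

#' SMD table over a covariate set
#'
#' Computes [smd()] for every covariate between two groups of a data frame.
#' Logical covariates use the binary formula on group proportions; numeric
#' covariates the continuous formula on group means/SDs; factors are
#' expanded into per-level indicators.
#'
#' @param data Covariate data (e.g. [baseline_covariates()] joined with a
#'   grouping column).
#' @param group Name of a two-level grouping column.
#' @param vars Covariate column names; default all logical/numeric/factor
#'   columns except identifiers and the group.
#' @return Tibble `variable`, `smd`, `abs_smd`, `negligible`
#'   (`abs_smd < 0.1`), ordered by decreasing `abs_smd`.  Sign convention:
#'   first group level minus second.
#' @export
smd_table <- function(data, group, vars = NULL) {
  g <- factor(data[[group]])
  stopifnot(nlevels(g) == 2)
  if (is.null(vars)) {
    vars <- setdiff(names(data)[map_lgl(data, \(x) {
      is.logical(x) || is.numeric(x) || is.factor(x)
    })], c(group, "person_id", "site_id"))
  }
  a <- g == levels(g)[1]
  rows <- map(vars, function(v) {
    x <- data[[v]]
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      map_dfr(levels(x), \(lv) tibble(
        variable = paste0(v, ":", lv),
        smd = smd(mean(x[a] == lv, na.rm = TRUE),
                  mean(x[!a] == lv, na.rm = TRUE), "binary")
      ))
    } else if (is.logical(x)) {
      tibble(variable = v,
             smd = smd(mean(x[a], na.rm = TRUE), mean(x[!a], na.rm = TRUE),
                       "binary"))
    } else {
      tibble(variable = v, smd = smd(
        c(mean(x[a], na.rm = TRUE), sd(x[a], na.rm = TRUE)),
        c(mean(x[!a], na.rm = TRUE), sd(x[!a], na.rm = TRUE)),
        "continuous"
      ))
    }
  })
  bind_rows(rows) |>
    mutate(abs_smd = abs(smd), negligible = abs_smd < 0.1) |>
    arrange(desc(abs_smd))
}

#' Stratified baseline table with tests across history groups
#'
#' The classic table-one layout: for each covariate, `n (%)` per group
#' (logical and categorical covariates, one row per level) or
#' `median (IQR)` (numeric covariates), with p-values from the
#' Kruskal-Wallis test (numeric) or the chi-square test of independence
#' (categorical), computed by the standard \pkg{stats} routines.  Cells with
#' positive counts below `suppress_below` are rendered `"<k"` (small-cell
#' suppression).  With a single non-empty group no tests are performed.
#'
#' @param data One row per patient, containing `group` and the covariates.
#' @param group Name of the grouping column.
#' @param vars Covariate column names.
#' @param suppress_below Suppression threshold (0 disables).
#' @return Tibble `variable`, `level`, one formatted column per group, and
#'   `p_value` (repeated down each variable's rows; `NA` without a test).
#' @export
history_table <- function(data, group, vars, suppress_below = 20) {
  g <- factor(data[[group]])
  g_levels <- levels(droplevels(g))
  n_by_g <- table(droplevels(g))
  multi <- length(g_levels) >= 2
  blocks <- map(vars, function(v) {
    x <- data[[v]]
    if (is.numeric(x)) {
      row <- tibble(variable = v, level = "median (IQR)")
      for (lv in g_levels) {
        row[[lv]] <- fmt_median_iqr(x[g == lv])
      }
      row$p_value <- if (multi) {
        suppressWarnings(kruskal.test(x, g)$p.value)
      } else NA_real_
      row
    } else {
      x <- if (is.logical(x)) factor(x, levels = c(TRUE, FALSE)) else factor(x)
      levels_shown <- if (is.logical(data[[v]])) "TRUE" else levels(x)
      p <- if (multi) {
        suppressWarnings(chisq.test(table(g, x))$p.value)
      } else NA_real_
      map_dfr(levels_shown, function(lv) {
        row <- tibble(variable = v, level = lv)
        for (gl in g_levels) {
          n <- sum(x[g == gl] == lv, na.rm = TRUE)
          row[[gl]] <- fmt_n_pct(n, n_by_g[[gl]], suppress_below)
        }
        row$p_value <- p
        row
      })
    }
  })
  bind_rows(blocks)
}

#' Fraction of no-history patients by site and pandemic month
#'
#' Cell = (# group-none patients) / (# cohort patients) per site and
#' calendar month of admission.  Site-months with no cohort patients are
#' absent from the output, not zero.
#'
#' @param cohort Output of [select_cohort()].
#' @param continuity Output of [months_prior_history()].
#' @return Tibble `site_id`, `month`, `n_patients`, `n_no_history`, `frac`.
#' @export
no_history_heatmap <- function(cohort, continuity) {
  cohort |>
    filter(included) |>
    inner_join(continuity |> select(person_id, history_group),
               by = "person_id") |>
    mutate(month = month_label(admission_date)) |>
    group_by(site_id, month) |>
    summarise(
      n_patients = n(),
      n_no_history = sum(history_group == "none"),
      frac = n_no_history / n_patients,
      .groups = "drop"
    )
}
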