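#' Configuration for the synthetic multi-site EHR generator
#'
#' Bundles every knob of [simulate_ehr_bundle()] with defaults that reproduce
#' the data pathologies documented for large multi-site COVID-19 EHR
#' repositories: heterogeneous per-site variable capture, calendar-time
#' modulation of missingness, duplicated / reversed / open drug-exposure
#' rows, single-day "Inferred from claim" truncation concentrated at one
#' site, variable prior-history depth with a hard lookback floor, comorbidity
#' prevalence gradients across history groups, and death dates offset from
#' visit end dates.
#'
#' @param n_sites Number of data partners.
#' @param patients_per_site Patients generated per site.
#' @param seed Integer seed; fully determines the output.
#' @param window Two dates bounding hospital admissions.
#' @param lookback_floor No generated event predates this date, so measurable
#'   history is right-capped by construction.
#' @param capture Per-site capture probabilities: named numeric vector over
#'   measurement variables (applied to every site), or a matrix with one row
#'   per site and one column per variable.  Default: the observed non-missing
#'   fractions of a hospitalized COVID-19 population, scaled across sites by
#'   `site_capture_gradient`.
#' @param site_capture_gradient Length-2 range of multiplicative site effects
#'   applied to a vector-valued `capture` (linear across sites, clipped to
#'   \[0, 1\]).  Ignored when `capture` is a matrix.
#' @param month_multipliers Optional matrix (sites x admission months of
#'   `window`) multiplying capture probabilities, for planting temporal
#'   missingness; default all 1.
#' @param paradigm Drug documentation paradigm per site:
#'   `"daily_duplicated"`, `"multiday_interval"` or `"mixed"`; recycled.
#' @param p_reversed Probability a multiday-documented course gains one
#'   reversed (end before start) row.
#' @param p_open Probability a duplicate single-day row has an absent end
#'   date (unbounded interval sharing the start date).
#' @param p_duplicate Probability each documented exposure day gains a
#'   duplicate row under the daily paradigm.
#' @param single_day_claim_fraction Fraction of treated patients whose course
#'   is documented only as its first day, tagged "Inferred from claim".
#' @param claim_site_share Target share of those truncated courses carried by
#'   the designated `claim_site`; capped at that site's treated count, with
#'   the remainder spread over the other sites (the realized fraction and
#'   share are recorded in the ground truth).
#' @param claim_site Index of the designated claim-artifact site.
#' @param history_weights Mixture weights over history groups
#'   `none` / `under_24` (uniform 1-23 months) / `cap_24plus` (>= 24 months).
#' @param comorbidity_prevalence Matrix of comorbidity prevalence by history
#'   group (rows = comorbidity, cols = `none`, `under_24`, `cap_24plus`).
#' @param med_prevalence Same layout for prior ACEI/ARB/statin use.
#' @param vent_prob,death_prob Named per-group probabilities of ventilation
#'   on admission and of true in-hospital death.
#' @param death_delta_probs Distribution of (recorded death date - visit end)
#'   offsets in days for true in-hospital deaths, named by integer offset.
#' @param p_posthosp_death Probability a survivor acquires an out-of-hospital
#'   death record 2-60 days after discharge.
#' @param p_subsequent_visit_artifact Probability a patient with a death
#'   record also has a spurious (billing-artifact) visit after the death date.
#' @param p_treated Probability of receiving the study drug (remdesivir).
#' @param course_length_probs Distribution of true course lengths in days,
#'   named by length.
#' @param p_missing_sex,p_missing_age Demographic missingness probabilities.
#' @param p_short_stay Probability of a 1-day stay (excluded by the cohort
#'   rules downstream).
#' @param p_ed_visit Probability of an emergency-department visit abutting
#'   the admission (exercises macrovisit merging).
#' @param p_split_stay Probability a stay is recorded as two overlapping
#'   inpatient visit rows.
#' @param p_carried_forward_mi Probability a patient's historical myocardial
#'   infarction is re-recorded on every day of the stay.
#' @param p_acute_mi Probability of a genuine acute in-hospital MI code.
#' @param date_shift Per-site date shift in days (recycled); also written to
#'   the site metadata as `max_date_shift_days`.
#' @param disposition_rate Per-site probability that a visit row carries a
#'   discharge disposition; default 0 for ACT-model sites and 0.4 otherwise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 6,
                       patients_per_site = 300,
                       seed = 1,
                       window = as.Date(c("2020-03-01", "2021-09-01")),
                       lookback_floor = as.Date("2018-01-01"),
                       capture = NULL,
                       site_capture_gradient = c(0.85, 1.1),
                       month_multipliers = NULL,
                       paradigm = NULL,
                       p_reversed = 0.05,
                       p_open = 0.3,
                       p_duplicate = 0.5,
                       single_day_claim_fraction = 0.55,
                       claim_site_share = 0.73,
                       claim_site = 1,
                       history_weights = c(none = 0.30, under_24 = 0.36, cap_24plus = 0.34),
                       comorbidity_prevalence = NULL,
                       med_prevalence = NULL,
                       vent_prob = c(none = 0.19, under_24 = 0.091, cap_24plus = 0.088),
                       death_prob = c(none = 0.14, under_24 = 0.11, cap_24plus = 0.11),
                       death_delta_probs = c(
                         `-3` = 0.005, `-2` = 0.005, `-1` = 0.06, `0` = 0.80,
                         `1` = 0.10, `2` = 0.02, `3` = 0.005, `4` = 0.005
                       ),
                       p_posthosp_death = 0.03,
                       p_subsequent_visit_artifact = 0.01,
                       p_treated = 0.6,
                       course_length_probs = c(`5` = 0.70, `10` = 0.15, `3` = 0.05, `4` = 0.05, `2` = 0.05),
                       p_missing_sex = 0.01,
                       p_missing_age = 0.01,
                       p_short_stay = 0.03,
                       p_ed_visit = 0.25,
                       p_split_stay = 0.15,
                       p_carried_forward_mi = 0.03,
                       p_acute_mi = 0.05,
                       date_shift = 0,
                       disposition_rate = NULL) {
  if (n_sites < 1 || patients_per_site < 1) {
    abort("infeasible config: need at least 1 site and 1 patient per site")
  }
  probs <- c(
    p_reversed, p_open, p_duplicate, single_day_claim_fraction,
    claim_site_share, p_posthosp_death, p_subsequent_visit_artifact,
    p_treated, p_missing_sex, p_missing_age, p_short_stay, p_ed_visit,
    p_split_stay, p_carried_forward_mi, p_acute_mi, vent_prob, death_prob
  )
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (abs(sum(history_weights) - 1) > 1e-8) {
    abort("history_weights must sum to 1")
  }
  stopifnot(
    length(window) == 2, window[1] < window[2],
    window[1] >= lookback_floor + 731 # >= 24 months of lookback available
  )
  groups <- c("none", "under_24", "cap_24plus")
  if (is.null(comorbidity_prevalence)) {
    comorbidity_prevalence <- rbind(
      hypertension    = c(0.45, 0.59, 0.74),
      diabetes        = c(0.33, 0.36, 0.45),
      cad             = c(0.11, 0.19, 0.30),
      chf             = c(0.13, 0.21, 0.30),
      copd            = c(0.074, 0.12, 0.18),
      cerebrovascular = c(0.068, 0.12, 0.19),
      ckd             = c(0.13, 0.22, 0.35),
      arrhythmia      = c(0.29, 0.35, 0.47),
      smoking         = c(0.061, 0.12, 0.12),
      malignancy      = c(0.059, 0.16, 0.21)
    )
    colnames(comorbidity_prevalence) <- groups
  }
  if (is.null(med_prevalence)) {
    med_prevalence <- rbind(
      acei   = c(0.039, 0.15, 0.25),
      arb    = c(0.031, 0.11, 0.19),
      statin = c(0.066, 0.26, 0.45)
    )
    colnames(med_prevalence) <- groups
  }
  cat_tbl <- measurement_catalog()
  if (is.null(capture)) {
    capture <- setNames(cat_tbl$capture, cat_tbl$variable)
  }
  if (is.matrix(capture)) {
    stopifnot(nrow(capture) == n_sites)
    capture <- capture[, cat_tbl$variable, drop = FALSE]
  } else {
    stopifnot(all(cat_tbl$variable %in% names(capture)))
    eff <- seq(site_capture_gradient[1], site_capture_gradient[2],
               length.out = n_sites)
    capture <- pmin(outer(eff, capture[cat_tbl$variable]), 1)
    colnames(capture) <- cat_tbl$variable
  }
  if (any(capture < 0 | capture > 1)) abort("capture probabilities must lie in [0, 1]")
  months <- seq(as.Date(cut(window[1], "month")), window[2], by = "month")
  if (is.null(month_multipliers)) {
    month_multipliers <- matrix(1, n_sites, length(months))
  }
  stopifnot(nrow(month_multipliers) == n_sites,
            ncol(month_multipliers) == length(months))
  colnames(month_multipliers) <- month_label(months)
  structure(
    list(
      n_sites = n_sites, patients_per_site = patients_per_site, seed = seed,
      window = window, lookback_floor = lookback_floor,
      capture = capture, month_multipliers = month_multipliers,
      paradigm = paradigm_per_site(
        paradigm %||% c("daily_duplicated", "multiday_interval", "mixed"),
        n_sites
      ),
      p_reversed = p_reversed, p_open = p_open, p_duplicate = p_duplicate,
      single_day_claim_fraction = single_day_claim_fraction,
      claim_site_share = claim_site_share, claim_site = claim_site,
      history_weights = history_weights,
      comorbidity_prevalence = comorbidity_prevalence,
      med_prevalence = med_prevalence,
      vent_prob = vent_prob, death_prob = death_prob,
      death_delta_probs = death_delta_probs / sum(death_delta_probs),
      p_posthosp_death = p_posthosp_death,
      p_subsequent_visit_artifact = p_subsequent_visit_artifact,
      p_treated = p_treated,
      course_length_probs = course_length_probs / sum(course_length_probs),
      p_missing_sex = p_missing_sex, p_missing_age = p_missing_age,
      p_short_stay = p_short_stay, p_ed_visit = p_ed_visit,
      p_split_stay = p_split_stay,
      p_carried_forward_mi = p_carried_forward_mi, p_acute_mi = p_acute_mi,
      date_shift = rep_len(as.integer(date_shift), n_sites),
      disposition_rate = disposition_rate
    ),
    class = "sim_config"
  )
}

# allow paradigm to be passed per-site as a character vector
paradigm_per_site <- function(paradigm, n_sites) {
  stopifnot(all(paradigm %in% c("daily_duplicated", "multiday_interval", "mixed")))
  rep_len(paradigm, n_sites)
}

#' Corrupt true drug courses into raw exposure rows
#'
#' Re-documents clean (start, end) treatment courses under the documentation
#' paradigms seen in multi-site EHR extracts: `daily_duplicated` emits one
#' single-day row per exposure day plus probabilistic duplicates, some with
#' absent end dates sharing the start date; `multiday_interval` splits the
#' course into 1-3 overlapping-or-abutting sub-intervals and may inject one
#' reversed (end before start) row; `mixed` picks a paradigm per course.
#' Reversed rows add no coverage, so drug-era reconstruction on the output
#' recovers each input course exactly.
#'
#' @param courses Tibble with columns `person_id`, `start_date`, `end_date`
#'   (non-overlapping per person); extra columns are carried through.
#' @param paradigm Scalar or per-course paradigm.
#' @param p_duplicate,p_open,p_reversed Corruption probabilities (see
#'   [sim_config()]).
#' @param seed Optional seed; `NULL` inherits the caller's RNG state.
#' @return Tibble of raw exposure rows: the carried-through columns plus
#'   `start_date`, `end_date` (possibly `NA` or reversed).
#' @export
corrupt_drug_documentation <- function(courses, paradigm,
                                       p_duplicate = 0.5, p_open = 0.3,
                                       p_reversed = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(courses) == 0) {
    return(mutate(courses[0, ], start_date = as.Date(character()),
                  end_date = as.Date(character())))
  }
  stopifnot(all(courses$end_date >= courses$start_date))
  courses <- courses |>
    mutate(
      .len = as.integer(end_date - start_date) + 1L,
      .par = paradigm_per_site(paradigm, n()),
      .par = if_else(.data$.par == "mixed",
                     sample_vec(c("daily_duplicated", "multiday_interval"), n()),
                     .data$.par),
      .cid = row_number()
    )
  extras <- setdiff(names(courses), c("start_date", "end_date", ".len", ".par"))

  # daily paradigm: one row per day, duplicates optionally open-ended
  daily <- courses |>
    filter(.data$.par == "daily_duplicated") |>
    uncount(.data$.len, .remove = FALSE, .id = ".day") |>
    mutate(day = start_date + .data$.day - 1L)
  daily_rows <- bind_rows(
    daily |> mutate(start_date = day, end_date = day),
    daily |>
      filter(runif(n()) < p_duplicate) |>
      mutate(
        start_date = day,
        end_date = if_else(runif(n()) < p_open, as.Date(NA), day)
      )
  ) |>
    select(all_of(extras), start_date, end_date)

  # multiday paradigm: split into k overlapping-or-abutting pieces
  multi <- courses |> filter(.data$.par == "multiday_interval")
  multi_rows <- NULL
  if (nrow(multi) > 0) {
    multi <- multi |>
      mutate(.k = pmin(sample_vec(1:3, n()), .data$.len))
    piece_list <- list(multi |> filter(.data$.k == 1))
    k2 <- multi |> filter(.data$.k == 2)
    if (nrow(k2) > 0) {
      cut1 <- k2$start_date + floor(runif(nrow(k2)) * (k2$.len - 1))
      lap <- runif(nrow(k2)) < 0.5 # share the boundary day or abut
      piece_list <- c(piece_list, list(
        k2 |> mutate(end_date = cut1),
        k2 |> mutate(start_date = as.Date(ifelse(lap, cut1, cut1 + 1L),
                                          origin = "1970-01-01"))
      ))
    }
    k3 <- multi |> filter(.data$.k == 3)
    if (nrow(k3) > 0) {
      c1 <- k3$start_date + floor(runif(nrow(k3)) * (k3$.len - 2))
      c2 <- c1 + 1L + floor(runif(nrow(k3)) * as.integer(k3$end_date - c1 - 1))
      piece_list <- c(piece_list, list(
        k3 |> mutate(end_date = c1),
        k3 |> mutate(start_date = c1 + 1L, end_date = c2),
        k3 |> mutate(start_date = c2 + 1L)
      ))
    }
    rev_src <- multi |> filter(.data$.len >= 2, runif(n()) < p_reversed)
    if (nrow(rev_src) > 0) {
      b <- rev_src$start_date + floor(runif(nrow(rev_src)) * (rev_src$.len - 1))
      piece_list <- c(piece_list, list(
        rev_src |> mutate(start_date = b + 1L, end_date = b)
      ))
    }
    multi_rows <- bind_rows(piece_list) |>
      filter(end_date >= start_date - 366) |> # keep reversed rows, drop nothing real
      select(all_of(extras), start_date, end_date)
  }
  bind_rows(daily_rows, multi_rows) |>
    select(-any_of(c(".len", ".par", ".day", ".k", "day", ".cid"))) |>
    arrange(across(any_of(c("person_id"))), start_date)
}

#' Generate a synthetic multi-site EHR bundle with ground truth
#'
#' Simulates one hospitalized-cohort extract per [sim_config()]: persons with
#' demographics, prior-history visits, an index hospitalization (optionally
#' split/abutted to exercise macrovisit merging), measurements thinned by
#' per-site capture probabilities and monthly multipliers, drug courses
#' corrupted by [corrupt_drug_documentation()] and claim truncation,
#' comorbidity/medication/ventilation codes with history-group gradients,
#' acute and carried-forward inpatient events, and death records offset from
#' visit ends.  The same seed always yields a byte-identical result.
#'
#' @param config A [sim_config()].
#' @return A list of class `ehr_sim`:
#' \describe{
#'   \item{bundle}{the [ehr_bundle()]}
#'   \item{index_events}{tibble `person_id`, `index_date` (first positive
#'     test; the phenotype itself is out of scope)}
#'   \item{truth}{ground truth: `persons` (planted history group, true and
#'     documented course, claim truncation, true in-hospital death flag,
#'     comorbidity flags, ...), `site_capture` (planted capture
#'     probabilities), `claim` (realized truncated fraction and site share),
#'     and the `config`}
#' }
#' @export
simulate_ehr_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_sites
  n <- S * config$patients_per_site
  site_ids <- sprintf("S%02d", seq_len(S))
  cdm <- rep_len(c("OMOP", "PCORnet", "ACT", "TriNetX"), S)
  disp_rate <- config$disposition_rate %||% ifelse(cdm == "ACT", 0, 0.4)
  disp_rate <- rep_len(disp_rate, S)

  site <- tibble(
    site_id = site_ids, source_cdm = cdm,
    max_date_shift_days = config$date_shift
  )

  ppl <- tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    site_idx = rep(seq_len(S), each = config$patients_per_site),
    site_id = site_ids[.data$site_idx]
  )

  # admissions and index dates -------------------------------------------
  span <- as.integer(config$window[2] - config$window[1]) - 40L
  ppl <- ppl |>
    mutate(
      admission = config$window[1] + sample.int(span + 1L, n, TRUE) - 1L,
      index_date = admission - sample_vec(0:3, n, prob = c(0.45, 0.3, 0.15, 0.1)),
      los = ifelse(runif(n) < config$p_short_stay, 1L, 2L + rpois(n, 5)),
      discharge = admission + los - 1L,
      age = pmax(18L, pmin(95L, round(rnorm(n, 62, 18)))),
      birth_year = date_year(index_date) - age,
      sex = sample_vec(c("female", "male"), n, prob = c(0.48, 0.52)),
      race = sample_vec(
        c("White", "Black or African American", "Asian", "Other/Unknown"),
        n, prob = c(0.52, 0.22, 0.035, 0.225)
      ),
      ethnicity = sample_vec(
        c("Not Hispanic or Latino", "Hispanic or Latino", "Unknown"),
        n, prob = c(0.74, 0.20, 0.06)
      ),
      birth_year = ifelse(runif(n) < config$p_missing_age, NA_integer_, birth_year),
      sex = ifelse(runif(n) < config$p_missing_sex, NA_character_, sex)
    )

  # prior history --------------------------------------------------------
  groups <- c("none", "under_24", "cap_24plus")
  ppl$history_group <- sample_vec(groups, n, prob = config$history_weights)
  m_under <- sample_vec(1:23, n)
  avail <- as.integer(ppl$admission - config$lookback_floor)
  days_prior <- dplyr::case_when(
    ppl$history_group == "none" ~ NA_integer_,
    ppl$history_group == "under_24" ~
      as.integer(ceiling(m_under * 30.4375) + sample_vec(0:24, n)),
    TRUE ~ as.integer(731L + floor(runif(n) * pmax(avail - 730L, 1L)))
  )
  days_prior <- pmin(days_prior, avail)
  # the hospital episode may start a day early when an abutting ED visit is
  # generated; realized history depth is measured from that episode start
  ppl <- ppl |>
    mutate(
      ed_visit = runif(n) < config$p_ed_visit,
      ed_offset = ifelse(ed_visit, sample_vec(0:1, n), 0L),
      stay_start = admission - ed_offset,
      days_prior = days_prior,
      earliest_visit = admission - days_prior,
      months_history = ifelse(
        is.na(days_prior), 0L,
        pmin(floor((days_prior - ed_offset) / 30.4375), 24L)
      ),
      history_group = case_when(
        is.na(days_prior) ~ "none",
        months_history >= 24L ~ "cap_24plus",
        TRUE ~ "under_24"
      )
    )

  prior_visits <- ppl |>
    filter(history_group != "none") |>
    mutate(n_prior = 1L + rpois(n(), 1.5)) |>
    uncount(.data$n_prior, .remove = FALSE, .id = ".j") |>
    mutate(
      start_date = if_else(
        .data$.j == 1L, earliest_visit,
        earliest_visit +
          floor(runif(n()) * pmax(as.integer(admission - 10L - earliest_visit), 1L))
      ),
      start_date = pmin(start_date, admission - 1L),
      end_date = start_date,
      visit_kind = "outpatient",
      discharge_disposition = NA_character_
    ) |>
    select(person_id, site_id, visit_kind, start_date, end_date,
           discharge_disposition)

  # index hospitalization rows -------------------------------------------
  disp_pool <- c("Home", "Skilled Nursing Facility", "Home Health", "Expired",
                 "Hospice", "Transfer to Acute Care", "Left Against Medical Advice",
                 "Rehabilitation Facility", "Long Term Acute Care", "Other")
  disp_prob <- c(0.50, 0.12, 0.10, 0.08, 0.05, 0.05, 0.04, 0.03, 0.02, 0.01)
  draw_disp <- function(k, rate) {
    ifelse(runif(k) < rate, sample_vec(disp_pool, k, prob = disp_prob),
           NA_character_)
  }
  ppl <- ppl |>
    mutate(split_stay = runif(n) < config$p_split_stay & los >= 4L)
  stay1 <- ppl |>
    mutate(
      start_date = admission,
      end_date = if_else(split_stay, admission + floor(los / 2), discharge),
      visit_kind = "inpatient",
      discharge_disposition = draw_disp(n, disp_rate[site_idx])
    )
  stay2 <- ppl |>
    filter(split_stay) |>
    mutate(
      start_date = admission + floor(los / 2), # overlaps stay1 on one day
      end_date = discharge,
      visit_kind = "inpatient",
      discharge_disposition = draw_disp(n(), disp_rate[site_idx])
    )
  ed <- ppl |>
    filter(ed_visit) |>
    mutate(
      start_date = .data$stay_start,
      end_date = admission,
      visit_kind = "emergency",
      discharge_disposition = NA_character_
    )
  stay_rows <- bind_rows(stay1, stay2, ed) |>
    select(person_id, site_id, visit_kind, start_date, end_date,
           discharge_disposition)

  # measurements ----------------------------------------------------------
  cat_tbl <- measurement_catalog()
  month_idx <- match(month_label(ppl$admission), colnames(config$month_multipliers))
  meas_list <- vector("list", nrow(cat_tbl))
  for (j in seq_len(nrow(cat_tbl))) {
    v <- cat_tbl$variable[j]
    p <- pmin(pmax(config$capture[ppl$site_idx, v] *
                     config$month_multipliers[cbind(ppl$site_idx, month_idx)], 0), 1)
    got <- runif(n) < p
    idx <- which(got)
    if (length(idx) == 0) next
    k <- length(idx)
    extra <- runif(k) < 0.4
    first <- tibble(
      person_id = ppl$person_id[idx], site_id = ppl$site_id[idx],
      variable = v,
      value = draw_measurement(cat_tbl[j, ], k),
      date = ppl$admission[idx] +
        sample_vec(0:1, k) * (ppl$los[idx] > 1L)
    )
    rep_rows <- tibble(
      person_id = ppl$person_id[idx][extra], site_id = ppl$site_id[idx][extra],
      variable = v,
      value = draw_measurement(cat_tbl[j, ], sum(extra)),
      date = ppl$admission[idx][extra] +
        floor(runif(sum(extra)) * ppl$los[idx][extra])
    )
    meas_list[[j]] <- bind_rows(first, rep_rows)
  }
  measurement <- bind_rows(meas_list)
  if (nrow(measurement) == 0) {
    measurement <- tibble(
      person_id = character(), site_id = character(), variable = character(),
      value = double(), date = as.Date(character())
    )
  }

  # drug exposures --------------------------------------------------------
  ppl$treated <- runif(n) < config$p_treated
  lens <- as.integer(names(config$course_length_probs))
  ppl <- ppl |>
    mutate(
      course_start = admission + pmin(sample_vec(0:2, n), los - 1L),
      course_len = sample_vec(lens, n, prob = config$course_length_probs),
      course_end = pmin(course_start + course_len - 1L, discharge)
    )
  treated_idx <- which(ppl$treated)
  trunc <- allocate_claim_truncation(
    ppl$site_idx[treated_idx], config$single_day_claim_fraction,
    config$claim_site_share, config$claim_site
  )
  ppl$claim_truncated <- FALSE
  ppl$claim_truncated[treated_idx[trunc]] <- TRUE
  ppl <- ppl |>
    mutate(
      doc_start = if_else(treated, course_start, as.Date(NA)),
      doc_end = case_when(
        !treated ~ as.Date(NA),
        claim_truncated ~ course_start,
        TRUE ~ course_end
      )
    )

  rem_concepts <- c(1001L, 1003L, 1004L, 1005L)
  rem_probs <- c(0.885, 0.105, 0.008, 0.0013)
  claim_courses <- ppl |>
    filter(claim_truncated) |>
    mutate(start_date = doc_start, end_date = doc_start) |>
    select(person_id, site_id, start_date, end_date)
  claim_rows <- claim_courses |>
    uncount(1L + rbinom(nrow(claim_courses), 1L, 0.6)) |>
    mutate(drug_type_label = "Inferred from claim")
  ehr_courses <- ppl |>
    filter(treated, !claim_truncated) |>
    mutate(start_date = doc_start, end_date = doc_end) |>
    select(person_id, site_id, site_idx, start_date, end_date)
  ehr_rows <- corrupt_drug_documentation(
    ehr_courses,
    paradigm = config$paradigm[ehr_courses$site_idx],
    p_duplicate = config$p_duplicate, p_open = config$p_open,
    p_reversed = config$p_reversed
  ) |>
    mutate(drug_type_label = ifelse(runif(n()) < 0.9, "EHR", NA_character_)) |>
    select(-site_idx)
  rem_rows <- bind_rows(claim_rows, ehr_rows) |>
    mutate(concept_id = sample_vec(rem_concepts, n(), prob = rem_probs))

  dex <- ppl |>
    filter(runif(n) < 0.35) |>
    mutate(
      start_date = admission + pmin(sample_vec(0:2, n()), los - 1L),
      end_date = pmin(start_date + sample_vec(1:9, n()), discharge),
      end_date = pmax(end_date, start_date),
      concept_id = sample_vec(c(1002L, 1006L, 1007L, 1008L), n(),
                              prob = c(0.41, 0.35, 0.22, 0.02)),
      drug_type_label = "EHR"
    ) |>
    select(person_id, site_id, concept_id, start_date, end_date, drug_type_label)

  med_names <- rownames(config$med_prevalence)
  med_ids <- c(acei = 5001L, arb = 5002L, statin = 5003L)
  ppl_meds <- vector("list", length(med_names))
  for (j in seq_along(med_names)) {
    has <- runif(n) < unname(config$med_prevalence[med_names[j], ppl$history_group])
    idx <- which(has)
    ppl[[paste0("med_", med_names[j])]] <- has
    if (length(idx) == 0) next
    start <- ppl$admission[idx] - sample_vec(60:400, length(idx))
    ppl_meds[[j]] <- tibble(
      person_id = ppl$person_id[idx], site_id = ppl$site_id[idx],
      concept_id = med_ids[[med_names[j]]],
      start_date = start, end_date = start + 30L,
      drug_type_label = "EHR"
    )
  }
  drug_exposure <- bind_rows(
    rem_rows |> select(person_id, site_id, concept_id, start_date, end_date,
                       drug_type_label),
    dex, bind_rows(ppl_meds)
  )

  # conditions ------------------------------------------------------------
  com_names <- rownames(config$comorbidity_prevalence)
  com_ids <- setNames(2001:2010, c(
    "hypertension", "diabetes", "cad", "chf", "copd", "cerebrovascular",
    "ckd", "arrhythmia", "smoking", "malignancy"
  ))
  cond_list <- vector("list", length(com_names) + 3L)
  for (j in seq_along(com_names)) {
    has <- runif(n) < unname(config$comorbidity_prevalence[com_names[j], ppl$history_group])
    ppl[[paste0("hx_", com_names[j])]] <- has
    idx <- which(has)
    if (length(idx) == 0) next
    cond_list[[j]] <- tibble(
      person_id = ppl$person_id[idx], site_id = ppl$site_id[idx],
      concept_id = as.integer(com_ids[[com_names[j]]]),
      date = ppl$admission[idx] - sample_vec(30:600, length(idx))
    )
  }
  ppl$ventilated <- runif(n) < unname(config$vent_prob[ppl$history_group])
  vent_idx <- which(ppl$ventilated)
  cond_list[[length(com_names) + 1L]] <- tibble(
    person_id = ppl$person_id[vent_idx], site_id = ppl$site_id[vent_idx],
    concept_id = ifelse(runif(length(vent_idx)) < 0.9, 3001L, 3002L),
    date = ppl$admission[vent_idx] +
      sample_vec(0:1, length(vent_idx)) * (ppl$los[vent_idx] > 1L)
  )
  acute_idx <- which(runif(n) < config$p_acute_mi & ppl$los >= 3L)
  cond_list[[length(com_names) + 2L]] <- tibble(
    person_id = ppl$person_id[acute_idx], site_id = ppl$site_id[acute_idx],
    concept_id = 4001L,
    date = ppl$admission[acute_idx] + 1L +
      floor(runif(length(acute_idx)) * (ppl$los[acute_idx] - 1L))
  )
  carried <- ppl |>
    filter(runif(n) < config$p_carried_forward_mi) |>
    uncount(.data$los, .remove = FALSE, .id = ".d") |>
    transmute(person_id, site_id, concept_id = 4001L,
              date = admission + .data$.d - 1L)
  cond_list[[length(com_names) + 3L]] <- carried
  condition_occurrence <- bind_rows(cond_list)

  # deaths ----------------------------------------------------------------
  ppl$died_in_hosp <- runif(n) < unname(config$death_prob[ppl$history_group])
  deltas <- as.integer(names(config$death_delta_probs))
  ppl$death_delta <- NA_integer_
  ih <- which(ppl$died_in_hosp)
  ppl$death_delta[ih] <- sample_vec(deltas, length(ih),
                                    prob = config$death_delta_probs)
  oh <- which(!ppl$died_in_hosp & runif(n) < config$p_posthosp_death)
  ppl$death_delta[oh] <- sample_vec(2:60, length(oh))
  has_death <- which(!is.na(ppl$death_delta))
  death <- tibble(
    person_id = ppl$person_id[has_death], site_id = ppl$site_id[has_death],
    death_date = ppl$discharge[has_death] + ppl$death_delta[has_death]
  )
  ppl$subsequent_visit_artifact <- FALSE
  art <- has_death[runif(length(has_death)) < config$p_subsequent_visit_artifact]
  ppl$subsequent_visit_artifact[art] <- TRUE
  artifact_visits <- tibble(
    person_id = ppl$person_id[art], site_id = ppl$site_id[art],
    visit_kind = "outpatient",
    start_date = ppl$discharge[art] + ppl$death_delta[art] + sample_vec(1:10, length(art)),
    end_date = NA, discharge_disposition = NA_character_
  ) |>
    mutate(end_date = start_date)

  visit_occurrence <- bind_rows(prior_visits, stay_rows, artifact_visits) |>
    arrange(person_id, start_date) |>
    mutate(visit_id = sprintf("V%07d", row_number()), .before = 1)

  # assemble --------------------------------------------------------------
  person <- ppl |>
    transmute(person_id, site_id, birth_year = as.integer(birth_year),
              sex, race, ethnicity)
  tables <- list(
    person = person,
    visit_occurrence = visit_occurrence,
    drug_exposure = drug_exposure,
    measurement = measurement,
    condition_occurrence = condition_occurrence,
    death = death,
    concept = sim_concepts(),
    concept_ancestor = sim_concept_ancestors(),
    site = site
  )
  # per-site date shift (metadata records the magnitude)
  shift <- config$date_shift
  if (any(shift != 0)) {
    shift_by_site <- setNames(shift, site_ids)
    tables[c("visit_occurrence", "drug_exposure", "measurement",
             "condition_occurrence", "death")] <-
      lapply(tables[c("visit_occurrence", "drug_exposure", "measurement",
                      "condition_occurrence", "death")], function(tbl) {
        dcols <- intersect(names(tbl), c("start_date", "end_date", "date", "death_date"))
        for (col in dcols) tbl[[col]] <- tbl[[col]] + shift_by_site[tbl$site_id]
        tbl
      })
  }

  truth_persons <- ppl |>
    select(person_id, site_id, admission, stay_start, discharge, los, index_date,
           history_group, months_history, treated, course_start, course_end,
           doc_start, doc_end, claim_truncated, died_in_hosp, death_delta,
           subsequent_visit_artifact, ventilated,
           starts_with("hx_"), starts_with("med_")) |>
    mutate(
      course_start = if_else(treated, course_start, as.Date(NA)),
      course_end = if_else(treated, course_end, as.Date(NA))
    )
  n_treated <- sum(ppl$treated)
  n_trunc <- sum(ppl$claim_truncated)
  truth <- list(
    persons = truth_persons,
    site_capture = as_tibble(config$capture) |>
      mutate(site_id = site_ids, .before = 1) |>
      pivot_longer(-site_id, names_to = "variable", values_to = "capture"),
    claim = list(
      fraction_planted = if (n_treated > 0) n_trunc / n_treated else NA_real_,
      site_share_planted = if (n_trunc > 0) {
        sum(ppl$claim_truncated & ppl$site_idx == config$claim_site) / n_trunc
      } else NA_real_
    ),
    config = config
  )
  structure(
    list(
      bundle = ehr_bundle(tables),
      index_events = ppl |> select(person_id, index_date),
      truth = truth
    ),
    class = "ehr_sim"
  )
}

draw_measurement <- function(row, k) {
  x <- if (row$dist == "lnorm") rlnorm(k, row$p1, row$p2) else rnorm(k, row$p1, row$p2)
  round(x, row$digits)
}

# Pick which treated patients get claim-truncated, concentrating the target
# share on the designated site but never exceeding a site's treated count.
allocate_claim_truncation <- function(site_idx, fraction, share, claim_site) {
  n <- length(site_idx)
  total <- round(fraction * n)
  if (total == 0 || n == 0) return(integer())
  at_claim <- which(site_idx == claim_site)
  q1 <- min(round(share * total), length(at_claim))
  others <- which(site_idx != claim_site)
  q2 <- min(total - q1, length(others))
  c(
    if (q1 > 0) sample_vec(at_claim, q1, replace = FALSE) else integer(),
    if (q2 > 0) sample_vec(others, q2, replace = FALSE) else integer()
  )
}

#' @export
print.ehr_sim <- function(x, ...) {
  cat("<ehr_sim>", nrow(x$truth$persons), "patients across",
      nrow(x$bundle$site), "sites\n")
  print(x$bundle)
  invisible(x)
}
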