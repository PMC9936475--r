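# EHR-continuity profiling, baseline covariates, SMDs, stratified tables

test_that("history groups follow the prior-visit and cap rules", {
  cohort <- dplyr::bind_rows(
    cohort_row("A", "2020-06-01", "2020-06-10"),  # no prior visit
    cohort_row("B", "2020-06-01", "2020-06-10"),  # 800 days of history
    cohort_row("C", "2020-06-01", "2020-06-10")   # same-day visit only
  )
  visits <- tibble::tibble(
    visit_id = c("V1", "V2"), person_id = c("B", "C"), site_id = "S01",
    visit_kind = "outpatient",
    start_date = as.Date(c("2020-06-01", "2020-06-01")) - c(800L, 0L),
    end_date = as.Date(NA), discharge_disposition = NA_character_
  )
  rec <- months_prior_history(visits, cohort)
  a <- rec[rec$person_id == "A", ]
  expect_equal(as.character(a$history_group), "none")
  expect_equal(a$months_prior_history, 0L)
  b <- rec[rec$person_id == "B", ]
  expect_equal(as.character(b$history_group), "cap_24plus")
  expect_equal(b$months_prior_history, 24L)
  # a visit on the admission day itself is not prior history
  expect_equal(as.character(rec$history_group[rec$person_id == "C"]), "none")
  # groups partition the cohort
  expect_equal(sum(table(rec$history_group)), nrow(cohort))
})

test_that("visits below the lookback floor are ignored", {
  cohort <- cohort_row("A", "2020-06-01", "2020-06-10")
  visits <- tibble::tibble(
    visit_id = "V1", person_id = "A", site_id = "S01",
    visit_kind = "outpatient", start_date = as.Date("2017-05-01"),
    end_date = as.Date(NA), discharge_disposition = NA_character_
  )
  rec <- months_prior_history(visits, cohort)
  expect_equal(as.character(rec$history_group), "none")
})

test_that("month counts match the brute-force day oracle on random pairs", {
  set.seed(71)
  n <- 1000
  admission <- as.Date("2020-03-01") + sample(0:500, n, replace = TRUE)
  earliest <- admission - sample(1:800, n, replace = TRUE)
  earliest <- pmax(earliest, as.Date("2018-01-01"))
  ok <- earliest < admission
  cohort <- dplyr::bind_rows(lapply(which(ok), function(i) {
    cohort_row(sprintf("P%04d", i), admission[i], admission[i] + 5)
  }))
  visits <- tibble::tibble(
    visit_id = sprintf("V%04d", which(ok)),
    person_id = sprintf("P%04d", which(ok)), site_id = "S01",
    visit_kind = "outpatient", start_date = earliest[ok],
    end_date = as.Date(NA), discharge_disposition = NA_character_
  )
  rec <- months_prior_history(visits, cohort) |> dplyr::arrange(person_id)
  expect_equal(rec$months_prior_history,
               unname(oracle_months(earliest[ok], admission[ok])))
})

test_that("the binary SMD formula reproduces its closed form", {
  # prevalences 0.74 vs 0.45 give SMD 0.618
  expect_equal(round(smd(0.74, 0.45, "binary"), 3), 0.618)
  expect_equal(smd(0.3, 0.3, "binary"), 0)
  # antisymmetry
  expect_equal(smd(0.74, 0.45, "binary"), -smd(0.45, 0.74, "binary"))
  expect_equal(smd(c(10, 2), c(8, 2), "continuous"),
               -smd(c(8, 2), c(10, 2), "continuous"))
  # identical degenerate groups compare as zero
  expect_equal(smd(0, 0, "binary"), 0)
  expect_equal(smd(c(5, 0), c(5, 0), "continuous"), 0)
  expect_equal(smd(c(10, 1), c(6, 3), "continuous"),
               4 / sqrt((1 + 9) / 2))
})

test_that("smd_table expands factors and flags negligible differences", {
  set.seed(73)
  n <- 500
  dat <- tibble::tibble(
    grp = rep(c("a", "b"), each = n),
    x = c(rbinom(n, 1, 0.74), rbinom(n, 1, 0.45)) == 1,
    age = c(rnorm(n, 60, 10), rnorm(n, 60, 10)),
    band = factor(sample(c("lo", "hi"), 2 * n, replace = TRUE))
  )
  tab <- smd_table(dat, "grp")
  expect_true(all(c("x", "age", "band:lo", "band:hi") %in% tab$variable))
  expect_false(tab$negligible[tab$variable == "x"])
  expect_true(tab$negligible[tab$variable == "age"])
  expect_equal(tab$smd[tab$variable == "band:lo"],
               -tab$smd[tab$variable == "band:hi"])
})

test_that("covariates are absent without prior records and windows bind", {
  cohort <- dplyr::bind_rows(
    cohort_row("A", "2020-06-01", "2020-06-10"),
    cohort_row("B", "2020-06-01", "2020-06-10")
  )
  conditions <- tibble::tibble(
    person_id = c("B", "B", "A"), site_id = "S01",
    concept_id = c(2001L, 3001L, 3001L),
    date = as.Date(c("2020-01-15", "2020-06-01", "2020-06-05"))
  )
  bundle <- make_bundle(
    person = tibble::tibble(
      person_id = c("A", "B"), site_id = "S01", birth_year = 1970L,
      sex = "female", race = NA_character_, ethnicity = NA_character_
    ),
    condition_occurrence = conditions,
    site = tibble::tibble(site_id = "S01", source_cdm = "OMOP",
                          max_date_shift_days = 0L)
  )
  covs <- baseline_covariates(bundle, cohort) |> dplyr::arrange(person_id)
  # A has no records before admission: every comorbidity indicator FALSE
  a <- covs[covs$person_id == "A", ]
  expect_false(any(unlist(a[, c("hypertension", "diabetes", "cad", "chf",
                                "copd", "ckd", "acei", "arb", "statin")])))
  expect_true(covs$hypertension[covs$person_id == "B"])
  # ventilation on day 1 counts, on day 5 does not
  expect_true(covs$ventilated_on_admission[covs$person_id == "B"])
  expect_false(covs$ventilated_on_admission[covs$person_id == "A"])
})

test_that("planted comorbidity gradients are recovered by history group", {
  sim <- sim_small()
  mv <- build_macrovisits(sim$bundle$visit_occurrence)
  cohort <- select_cohort(sim$bundle, mv, sim$index_events)
  cont <- months_prior_history(sim$bundle$visit_occurrence, cohort)
  # pipeline groups equal the planted groups person for person
  truth <- sim$truth$persons |>
    dplyr::semi_join(cohort |> dplyr::filter(included), by = "person_id")
  joined <- cont |>
    dplyr::inner_join(truth |> dplyr::select(person_id, history_group),
                      by = "person_id", suffix = c("", "_true"))
  expect_equal(as.character(joined$history_group), joined$history_group_true)

  covs <- baseline_covariates(sim$bundle, cohort)
  by_grp <- covs |>
    dplyr::inner_join(cont, by = "person_id") |>
    dplyr::group_by(history_group) |>
    dplyr::summarise(p = mean(hypertension))
  prev <- sim$truth$config$comorbidity_prevalence["hypertension", ]
  expect_true(all(abs(by_grp$p - prev[as.character(by_grp$history_group)]) < 0.12))
  # and the indicators themselves match the planted flags exactly
  flags <- covs |>
    dplyr::inner_join(truth |> dplyr::select(person_id, hx_hypertension),
                      by = "person_id")
  expect_equal(flags$hypertension, flags$hx_hypertension)
})

test_that("history tables format, suppress and test group differences", {
  set.seed(79)
  n <- 300
  dat <- tibble::tibble(
    grp = rep(c("none", "under_24", "cap_24plus"), each = n),
    age = rnorm(3 * n, 60, 12),
    hypertension = runif(3 * n) < rep(c(0.45, 0.59, 0.74), each = n),
    rare = c(runif(n) < 0.02, rep(FALSE, 2 * n))
  )
  tab <- history_table(dat, "grp", c("age", "hypertension", "rare"),
                       suppress_below = 20)
  expect_equal(tab$level[tab$variable == "age"], "median (IQR)")
  expect_match(tab$none[tab$variable == "age"], "^\\d+\\.\\d \\(")
  # strong planted gradient: significant chi-square
  expect_lt(tab$p_value[tab$variable == "hypertension"][1], 1e-6)
  # cell of ~6 < 20 suppressed
  expect_equal(tab$none[tab$variable == "rare"], "<20")
})

test_that("identical groups do not flood the table with significance", {
  set.seed(83)
  n <- 400
  dat <- tibble::tibble(
    grp = rep(c("a", "b"), each = n),
    v1 = runif(2 * n) < 0.3, v2 = runif(2 * n) < 0.5,
    v3 = runif(2 * n) < 0.1, v4 = runif(2 * n) < 0.7,
    age = rnorm(2 * n, 60, 10)
  )
  tab <- history_table(dat, "grp", c("v1", "v2", "v3", "v4", "age"),
                       suppress_below = 0)
  p <- unique(tab$p_value)
  expect_true(all(p > 1e-4))
  expect_gt(median(p), 0.05)
})

test_that("a single group yields a table without p-values", {
  dat <- tibble::tibble(grp = "only", x = c(TRUE, FALSE, TRUE))
  tab <- history_table(dat, "grp", "x", suppress_below = 0)
  expect_true(all(is.na(tab$p_value)))
})

test_that("the no-history heatmap distinguishes empty cells from zero", {
  cohort <- dplyr::bind_rows(
    cohort_row("A", "2020-06-01", "2020-06-10", site_id = "S01"),
    cohort_row("B", "2020-07-01", "2020-07-10", site_id = "S01"),
    cohort_row("C", "2020-06-15", "2020-06-20", site_id = "S02")
  )
  cont <- tibble::tibble(
    person_id = c("A", "B", "C"),
    earliest_visit_date = as.Date(c(NA, "2019-01-01", "2019-01-01")),
    months_prior_history = c(0L, 17L, 17L),
    history_group = factor(c("none", "under_24", "under_24"),
                           levels = c("none", "under_24", "cap_24plus"))
  )
  hm <- no_history_heatmap(cohort, cont)
  expect_equal(nrow(hm), 3L) # no row for the empty S02 x 2020-07 cell
  expect_equal(hm$frac[hm$site_id == "S01" & hm$month == "2020-06"], 1)
  expect_equal(hm$frac[hm$site_id == "S02" & hm$month == "2020-06"], 0)
  expect_false(any(hm$site_id == "S02" & hm$month == "2020-07"))
})

test_that("a planted month-specific no-history spike is reproduced", {
  sim <- sim_small()
  mv <- build_macrovisits(sim$bundle$visit_occurrence)
  cohort <- select_cohort(sim$bundle, mv, sim$index_events)
  cont <- months_prior_history(sim$bundle$visit_occurrence, cohort)
  hm <- no_history_heatmap(cohort, cont)
  truth <- sim$truth$persons |>
    dplyr::semi_join(cohort |> dplyr::filter(included), by = "person_id") |>
    dplyr::mutate(month = format(stay_start, "%Y-%m")) |>
    dplyr::group_by(site_id, month) |>
    dplyr::summarise(frac_true = mean(history_group == "none"), .groups = "drop")
  joined <- dplyr::inner_join(hm, truth, by = c("site_id", "month"))
  expect_equal(nrow(joined), nrow(hm))
  expect_equal(joined$frac, joined$frac_true)
})
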