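# site fitness screening: completeness, temporal missingness, clustering,
# exclusion rules

comp_tbl <- function(sites, vals, variables = key_vitals()) {
  tidyr::crossing(site_id = sites, variable = variables) |>
    dplyr::arrange(site_id, variable) |>
    dplyr::mutate(
      n_patients = 100L,
      completeness = rep(vals, each = length(variables)),
      n_with_value = as.integer(completeness)
    )
}

temp_tbl <- function(sites, months, frac, variables = key_vitals()) {
  tidyr::crossing(site_id = sites, month = months, variable = variables) |>
    dplyr::mutate(n_patients = 50L, frac_missing = frac)
}

site_meta_tbl <- function(sites, shift = 0L) {
  tibble::tibble(site_id = sites, source_cdm = "OMOP",
                 max_date_shift_days = rep_len(as.integer(shift), length(sites)))
}

test_that("completeness and whole-visit missingness are complements", {
  sim <- cached_sim("one_site", sim_config(n_sites = 1, patients_per_site = 200,
                                           seed = 33))
  mv <- build_macrovisits(sim$bundle$visit_occurrence)
  cohort <- select_cohort(sim$bundle, mv, sim$index_events)
  comp <- completeness_matrix(sim$bundle, cohort)
  miss <- patient_missingness_table(sim$bundle, cohort, window = "whole_visit")
  joined <- dplyr::inner_join(comp, miss, by = "variable")
  expect_equal(joined$pct_missing, 100 - joined$completeness)
})

test_that("the admission-window restriction excludes later values", {
  cohort <- cohort_row("A", "2020-06-01", "2020-06-10")
  meas <- tibble::tibble(
    person_id = "A", site_id = "S01", variable = "creatinine",
    value = 1.2, date = as.Date("2020-06-05") # day 5 of the stay
  )
  bundle <- make_bundle(
    person = tibble::tibble(person_id = "A", site_id = "S01",
                            birth_year = 1970L, sex = "female",
                            race = NA, ethnicity = NA),
    measurement = meas,
    site = site_meta_tbl("S01")
  )
  whole <- patient_missingness_table(bundle, cohort, "creatinine",
                                     window = "whole_visit")
  admit <- patient_missingness_table(bundle, cohort, "creatinine",
                                     window = "admission_2d")
  expect_equal(whole$n_nonmissing, 1L)
  expect_equal(admit$n_nonmissing, 0L)
  expect_equal(admit$pct_missing, 100)
})

test_that("an unrecorded variable is 100% missing with an NA summary", {
  cohort <- cohort_row("A", "2020-06-01", "2020-06-10")
  bundle <- make_bundle(
    person = tibble::tibble(person_id = "A", site_id = "S01",
                            birth_year = 1970L, sex = "female",
                            race = NA, ethnicity = NA),
    site = site_meta_tbl("S01")
  )
  tab <- patient_missingness_table(bundle, cohort, c("ferritin", "crp"))
  expect_equal(tab$pct_missing, c(100, 100))
  expect_true(all(is.na(tab$median)))
})

test_that("a planted lognormal creatinine median is recovered", {
  sim <- cached_sim("one_site", sim_config(n_sites = 1, patients_per_site = 200,
                                           seed = 33))
  mv <- build_macrovisits(sim$bundle$visit_occurrence)
  cohort <- select_cohort(sim$bundle, mv, sim$index_events)
  tab <- patient_missingness_table(sim$bundle, cohort, "creatinine")
  # planted log-normal with median 0.94; n ~ 85 observed values
  expect_lt(abs(tab$median - 0.94), 0.2)
})

test_that("identical sites merge at distance zero and clustering is
           permutation invariant", {
  comp <- comp_tbl(c("S01", "S02", "S03"), c(80, 80, 20))
  cl <- cluster_sites(comp)
  expect_equal(min(cl$tree$height), 0)
  same <- cl$labels |> dplyr::filter(site_id %in% c("S01", "S02"))
  expect_equal(same$cluster[1], same$cluster[2])
  expect_true(all(same$retained))
  expect_false(cl$labels$retained[cl$labels$site_id == "S03"])

  perm <- cluster_sites(comp |> dplyr::arrange(dplyr::desc(site_id)))
  expect_equal(
    perm$labels |> dplyr::arrange(site_id) |> dplyr::pull(retained),
    cl$labels |> dplyr::arrange(site_id) |> dplyr::pull(retained)
  )
})

test_that("clustering recovers a planted two-population site design", {
  cap <- matrix(rep(measurement_catalog()$capture, each = 8), nrow = 8,
                dimnames = list(NULL, measurement_variables()))
  cap[5:8, key_vitals()] <- 0.25  # low-capture population
  sim <- cached_sim("two_pop", sim_config(
    n_sites = 8, patients_per_site = 120, seed = 55, capture = cap
  ))
  mv <- build_macrovisits(sim$bundle$visit_occurrence)
  cohort <- select_cohort(sim$bundle, mv, sim$index_events)
  comp <- completeness_matrix(sim$bundle, cohort, key_vitals())
  cl <- cluster_sites(comp, k = 2)
  labels <- cl$labels |> dplyr::arrange(site_id)
  expect_equal(labels$retained, rep(c(TRUE, FALSE), each = 4))
})

test_that("a single site forms one trivial retained cluster", {
  cl <- cluster_sites(comp_tbl("S01", 50))
  expect_equal(nrow(cl$labels), 1L)
  expect_true(cl$labels$retained)
})

test_that("identical sites produce no exclusions (zero-SD edge case)", {
  sites <- sprintf("S%02d", 1:5)
  out <- apply_exclusion_rules(
    comp_tbl(sites, rep(60, 5)),
    temp_tbl(sites, c("2020-03", "2020-04"), 0.4),
    site_meta_tbl(sites)
  )
  expect_false(any(out$excluded))
  expect_true(all(out$reasons == ""))
})

test_that("each exclusion rule fires for its planted offender", {
  sites <- sprintf("S%02d", 1:10)
  vals <- c(rep(80, 8), 15, 80)        # site 9: only ~15% complete
  comp <- comp_tbl(sites, vals)
  temp <- temp_tbl(sites, sprintf("2020-%02d", 3:6), 0.2) |>
    dplyr::mutate(frac_missing = ifelse(
      site_id == "S03", rep(c(0.05, 0.95), length.out = dplyr::n()),
      frac_missing
    ))
  meta <- site_meta_tbl(sites) |>
    dplyr::mutate(max_date_shift_days = ifelse(site_id == "S07", 10L, 0L))
  out <- apply_exclusion_rules(comp, temp, meta)
  get_reasons <- function(s) strsplit(out$reasons[out$site_id == s], ";")[[1]]
  expect_true("vitals_below_threshold" %in% get_reasons("S09"))
  expect_true("missing_gt_2sd" %in% get_reasons("S09"))
  expect_true("temporal_var_gt_2sd" %in% get_reasons("S03"))
  expect_true("date_shift_gt_7d" %in% get_reasons("S07"))
  expect_equal(sort(out$site_id[out$excluded]), c("S03", "S07", "S09"))
  expect_equal(out$excluded, out$reasons != "")
})

test_that("exclusion rules are scale-free in patient counts", {
  sites <- sprintf("S%02d", 1:6)
  comp <- comp_tbl(sites, c(85, 80, 75, 70, 20, 90))
  temp <- temp_tbl(sites, c("2020-03", "2020-04", "2020-05"), 0.3)
  meta <- site_meta_tbl(sites)
  base <- apply_exclusion_rules(comp, temp, meta)
  doubled <- apply_exclusion_rules(
    comp |> dplyr::mutate(n_patients = n_patients * 2L,
                          n_with_value = n_with_value * 2L),
    temp |> dplyr::mutate(n_patients = n_patients * 2L),
    meta
  )
  expect_equal(base$excluded, doubled$excluded)
  expect_equal(base$reasons, doubled$reasons)
})

test_that("with a single identical month the temporal rule cannot fire", {
  sites <- sprintf("S%02d", 1:4)
  out <- apply_exclusion_rules(
    comp_tbl(sites, c(90, 85, 80, 75)),
    temp_tbl(sites, "2020-03", 0.25),
    site_meta_tbl(sites)
  )
  expect_true(all(out$temporal_variance == 0))
  expect_false(any(grepl("temporal_var", out$reasons)))
})

test_that("cluster dropout is reported when a clustering is supplied", {
  comp <- comp_tbl(c("S01", "S02", "S03", "S04"), c(90, 88, 25, 20))
  cl <- cluster_sites(comp)
  out <- apply_exclusion_rules(
    comp, temp_tbl(c("S01", "S02", "S03", "S04"), c("2020-03", "2020-04"), 0.2),
    site_meta_tbl(c("S01", "S02", "S03", "S04")),
    clusters = cl
  )
  expect_true(all(grepl("cluster_dropout",
                        out$reasons[out$site_id %in% c("S03", "S04")])))
  expect_false(any(grepl("cluster_dropout",
                         out$reasons[out$site_id %in% c("S01", "S02")])))
})
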