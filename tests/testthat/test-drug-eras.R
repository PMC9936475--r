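# ingredient roll-up, concept distributions, and drug-era reconstruction

drug_rows <- function(spans, person_id = "A", label = NA_character_) {
  tibble::tibble(
    person_id = person_id, site_id = "S01", concept_id = 1001L,
    start_date = as.Date(vapply(spans, `[[`, "", 1)),
    end_date = as.Date(vapply(spans, function(s) {
      if (length(s) > 1) s[[2]] else NA_character_
    }, "")),
    drug_type_label = rep_len(label, length(spans))
  )
}

test_that("descendant sets are transitive closures including the ingredient", {
  con <- sim_concepts()
  anc <- sim_concept_ancestors()
  # a leaf ingredient is its own only descendant
  expect_equal(descendants_of_ingredient(con, anc, 5001L), 5001L)
  # chain: remdesivir -> clinical drug -> branded drug
  expect_equal(descendants_of_ingredient(con, anc, 1001L),
               c(1001L, 1003L, 1004L, 1005L))
  expect_error(descendants_of_ingredient(con, anc, 1003L), "ingredient level")
  expect_error(descendants_of_ingredient(con, anc, 99L), "not found")
})

test_that("descendant sets match graph reachability on random hierarchies", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:20) {
    n <- 30L
    ids <- seq_len(n)
    # random DAG: edges only from lower to higher id
    from <- sample(ids[-n], 60, replace = TRUE)
    to <- vapply(from, function(f) sample((f + 1):n, 1), 1L)
    anc <- dplyr::distinct(tibble::tibble(
      ancestor_id = c(ids, from), descendant_id = c(ids, to)
    ))
    con <- tibble::tibble(concept_id = ids, concept_name = as.character(ids),
                          level = "ingredient")
    root <- sample(ids, 1)
    expect_equal(
      descendants_of_ingredient(con, anc, root),
      oracle_descendants(anc, root)
    )
  }
})

test_that("concept distributions count exactly", {
  rows <- tibble::tibble(
    person_id = "A", site_id = "S01",
    concept_id = rep(c(1001L, 1003L, 1004L), c(885, 100, 15)),
    start_date = as.Date("2020-06-01"), end_date = as.Date("2020-06-01"),
    drug_type_label = NA_character_
  )
  dist <- concept_distribution(rows, sim_concepts(), c(1001L, 1003L, 1004L, 1005L))
  expect_equal(dist$concept_name[1], "remdesivir")
  expect_equal(dist$percent, c(88.5, 10.0, 1.5))
  expect_equal(sum(dist$percent), 100)
  # empty row set -> empty distribution
  expect_equal(nrow(concept_distribution(rows[0, ], sim_concepts(), 1001L)), 0L)
})

test_that("duplicated single-day rows consolidate into one five-day era", {
  days <- as.character(seq(as.Date("2020-12-31"), as.Date("2021-01-04"), "day"))
  spans <- c(
    lapply(days, function(d) c(d, d)),       # bounded one-day rows
    lapply(days, function(d) c(d, d)),       # exact duplicates
    lapply(days[1:3], function(d) d)         # unbounded rows, same starts
  )
  eras <- build_drug_eras(drug_rows(spans))
  expect_equal(nrow(eras$eras), 1L)
  expect_equal(eras$eras$exposure_days, 5L)
  expect_equal(eras$eras$start_date, as.Date("2020-12-31"))
  expect_equal(eras$eras$end_date, as.Date("2021-01-04"))
  log <- setNames(eras$log$n, eras$log$action)
  expect_equal(log[["discarded_reversed"]], 0L)
  expect_equal(log[["open_as_single_day"]], 3L)
  expect_equal(log[["duplicates_removed"]], 8L)
})

test_that("a reversed row is discarded and the multi-day rows still give 5 days", {
  eras <- build_drug_eras(drug_rows(list(
    c("2020-11-23", "2020-11-24"),
    c("2020-11-24", "2020-11-23"),  # reversed: start after end
    c("2020-11-24", "2020-11-27")
  )))
  expect_equal(nrow(eras$eras), 1L)
  expect_equal(eras$eras$exposure_days, 5L)
  expect_equal(eras$log$n[eras$log$action == "discarded_reversed"], 1L)
})

test_that("era day coverage equals the union-of-day-sets oracle on dirty rows", {
  rows <- make_dirty_rows(300, seed = 41)
  built <- build_drug_eras(rows)
  expect_identical(era_day_sets(built$eras), oracle_day_sets(rows))
  # total covered days conserved
  expect_equal(sum(built$eras$exposure_days),
               sum(lengths(oracle_day_sets(rows))))
})

test_that("era building is idempotent and order invariant", {
  rows <- make_dirty_rows(100, seed = 43)
  built <- build_drug_eras(rows)$eras
  again <- build_drug_eras(
    built |> dplyr::transmute(person_id, site_id, start_date, end_date,
                              drug_type_label = NA_character_)
  )$eras
  expect_equal(again$start_date, built$start_date)
  expect_equal(again$end_date, built$end_date)
  set.seed(47)
  shuffled <- rows[sample.int(nrow(rows)), ]
  expect_equal(build_drug_eras(shuffled)$eras, built)
})

test_that("era count is non-increasing in the merge gap", {
  rows <- make_dirty_rows(200, seed = 51)
  n0 <- nrow(build_drug_eras(rows, gap_days = 0)$eras)
  n7 <- nrow(build_drug_eras(rows, gap_days = 7)$eras)
  n30 <- nrow(build_drug_eras(rows, gap_days = 30)$eras)
  expect_true(n30 <= n7 && n7 <= n0)
  # outpatient-style persistence merges what the inpatient gap keeps apart
  far <- drug_rows(list(c("2020-06-01", "2020-06-03"),
                        c("2020-06-20", "2020-06-22")))
  expect_equal(nrow(build_drug_eras(far, 0)$eras), 2L)
  expect_equal(nrow(build_drug_eras(far, 30)$eras), 1L)
})

test_that("duration histograms respect the terminal filter", {
  cohort <- dplyr::bind_rows(
    cohort_row("A", "2020-06-01", "2020-06-10"),
    cohort_row("B", "2020-06-01", "2020-06-10"),
    cohort_row("C", "2020-06-01", "2020-06-10")
  )
  eras <- build_drug_eras(dplyr::bind_rows(
    drug_rows(list(c("2020-06-02", "2020-06-06")), person_id = "A"),
    drug_rows(list(c("2020-06-06", "2020-06-10")), person_id = "B"), # ends at discharge
    drug_rows(list(c("2020-06-02", "2020-06-04")), person_id = "C")  # ends at death
  ))
  deaths <- tibble::tibble(person_id = "C", site_id = "S01",
                           death_date = as.Date("2020-06-04"))
  all_hist <- duration_distribution(eras, cohort, deaths)
  expect_equal(all_hist,
               tibble::tibble(duration_days = c(3L, 5L), n = c(1L, 2L),
                              prop = c(1 / 3, 2 / 3)))
  filt <- duration_distribution(eras, cohort, deaths,
                                "drop_if_ends_at_discharge_or_death")
  expect_equal(filt$duration_days, 5L)
  expect_equal(filt$n, 1L)
})

test_that("single-day era provenance is tallied with missing labels", {
  rows <- dplyr::bind_rows(
    drug_rows(list(c("2020-06-01", "2020-06-01")), "A", "Inferred from claim"),
    drug_rows(list(c("2020-06-01", "2020-06-01")), "B", NA_character_),
    drug_rows(list(c("2020-06-01", "2020-06-05")), "C", "EHR")
  )
  built <- build_drug_eras(rows)
  tab <- claim_inferred_breakdown(built)
  expect_setequal(tab$drug_type_label, c("Inferred from claim", "missing"))
  expect_equal(sum(tab$n), 2L)
  # no single-day eras -> empty table
  none <- build_drug_eras(drug_rows(list(c("2020-06-01", "2020-06-05"))))
  expect_equal(nrow(claim_inferred_breakdown(none)), 0L)
})

test_that("a planted claim-site concentration is reproduced", {
  sim <- cached_sim("claim", sim_config(
    n_sites = 3, patients_per_site = 400, seed = 61,
    single_day_claim_fraction = 0.25, claim_site_share = 0.73
  ))
  desc <- descendants_of_ingredient(sim$bundle$concept,
                                    sim$bundle$concept_ancestor, 1001L)
  built <- build_drug_eras(
    sim$bundle$drug_exposure |> dplyr::filter(concept_id %in% desc)
  )
  tab <- claim_inferred_breakdown(built) |>
    dplyr::filter(drug_type_label == "Inferred from claim")
  share_s01 <- tab$n[tab$site_id == "S01"] / sum(tab$n)
  expect_equal(sim$truth$claim$site_share_planted, 0.73, tolerance = 0.01)
  expect_lt(abs(share_s01 - sim$truth$claim$site_share_planted), 0.08)
  # over 80% of single-day-era source rows carry the claim label
  full <- claim_inferred_breakdown(built)
  expect_gt(sum(tab$n) / sum(full$n), 0.8)
})

test_that("tidy and glance summarise an era build", {
  rows <- make_dirty_rows(50, seed = 63)
  built <- build_drug_eras(rows)
  expect_identical(tidy(built), built$eras)
  g <- glance(built)
  expect_equal(g$n_eras, nrow(built$eras))
  expect_equal(g$total_exposure_days, sum(built$eras$exposure_days))
})
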