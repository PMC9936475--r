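# Independent brute-force oracles and shared fixtures.

# day-set oracle: per person, the set of covered days of a row set after the
# era cleaning rules 1-2 (drop reversed, open -> single day), enumerated day
# by day
oracle_day_sets <- function(rows) {
  rows <- rows[is.na(rows$end_date) | rows$end_date >= rows$start_date, ]
  rows$end_date[is.na(rows$end_date)] <- rows$start_date[is.na(rows$end_date)]
  split(rows, rows$person_id) |>
    lapply(function(df) {
      sort(unique(unlist(Map(
        function(s, e) seq(as.integer(s), as.integer(e)),
        df$start_date, df$end_date
      ))))
    })
}

# day sets covered by a set of eras (or macrovisits)
era_day_sets <- function(eras) {
  split(eras, eras$person_id) |>
    lapply(function(df) {
      sort(unique(unlist(Map(
        function(s, e) seq(as.integer(s), as.integer(e)),
        df$start_date, df$end_date
      ))))
    })
}

# calendar month-count oracle: whole months of `month_length` days between
# two dates, computed day by day
oracle_months <- function(earliest, admission, month_length = 30.4375,
                          cap = 24L) {
  pmin(floor(as.integer(admission - earliest) / month_length), cap)
}

# graph-reachability oracle for the concept hierarchy
oracle_descendants <- function(ancestors, id) {
  edges <- ancestors[ancestors$ancestor_id != ancestors$descendant_id, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$ancestor_id),
               to = as.character(edges$descendant_id)),
    vertices = data.frame(name = as.character(unique(
      c(ancestors$ancestor_id, ancestors$descendant_id, id)
    )))
  )
  sort(as.integer(names(igraph::subcomponent(g, as.character(id), "out"))))
}

# random dirty drug-exposure rows with planted reversals, open ends and
# duplicates, one row set per person
make_dirty_rows <- function(n_people, seed) {
  set.seed(seed)
  base <- as.Date("2020-06-01")
  rows <- lapply(seq_len(n_people), function(i) {
    k <- sample(1:6, 1)
    start <- base + sample(0:20, k, replace = TRUE)
    end <- start + sample(0:5, k, replace = TRUE)
    rev_i <- runif(k) < 0.2 & end > start
    tmp <- start[rev_i]
    start[rev_i] <- end[rev_i]
    end[rev_i] <- tmp
    end[runif(k) < 0.2] <- NA
    df <- data.frame(person_id = sprintf("P%04d", i),
                     start_date = start, end_date = end)
    df[rep(seq_len(k), 1 + (runif(k) < 0.3)), ] # duplicate some rows
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# a zero-row, correctly typed version of every dialect table
blank_tables <- function() {
  lapply(ehr_schema(), function(def) {
    cols <- lapply(unname(def$cols), function(tp) {
      switch(tp,
        character = character(), integer = integer(),
        double = double(), date = as.Date(character())
      )
    })
    names(cols) <- names(def$cols)
    tibble::as_tibble(cols)
  })
}

# minimal bundle: supplied tables override blanks; concept tables default to
# the generator's toy vocabulary so concept ids resolve
make_bundle <- function(...) {
  tabs <- blank_tables()
  tabs$concept <- sim_concepts()
  tabs$concept_ancestor <- sim_concept_ancestors()
  over <- list(...)
  for (nm in names(over)) {
    tabs[[nm]] <- dplyr::bind_rows(tabs[[nm]], over[[nm]])
  }
  ehr_bundle(tabs)
}

# a ready-made included-cohort row, for functions that consume cohorts
cohort_row <- function(person_id, admission, discharge,
                       site_id = "S01", included = TRUE) {
  tibble::tibble(
    person_id = person_id, site_id = site_id,
    index_date = as.Date(admission),
    macrovisit_id = paste0(person_id, "-M1"),
    admission_date = as.Date(admission), discharge_date = as.Date(discharge),
    length_days = as.integer(as.Date(discharge) - as.Date(admission)) + 1L,
    age_at_index = 50L, sex = "female",
    flag_demographics = TRUE, flag_adult = TRUE, flag_index_plausible = TRUE,
    flag_hospitalized = TRUE, flag_min_stay = TRUE, included = included
  )
}

# one-patient mortality scenario: the call for a death `delta` days after
# the visit end (NA = no death record), optionally with a spurious later visit
mort_case <- function(delta = NA, subsequent = FALSE) {
  cohort <- cohort_row("A", "2020-06-01", "2020-06-10")
  deaths <- if (is.na(delta)) {
    tibble::tibble(person_id = character(), site_id = character(),
                   death_date = as.Date(character()))
  } else {
    tibble::tibble(person_id = "A", site_id = "S01",
                   death_date = as.Date("2020-06-10") + delta)
  }
  visits <- tibble::tibble(
    visit_id = "V1", person_id = "A", site_id = "S01",
    visit_kind = "inpatient", start_date = as.Date("2020-06-01"),
    end_date = as.Date("2020-06-10"), discharge_disposition = NA_character_
  )
  if (subsequent) {
    visits <- dplyr::bind_rows(visits, tibble::tibble(
      visit_id = "V2", person_id = "A", site_id = "S01",
      visit_kind = "outpatient",
      start_date = deaths$death_date + 5, end_date = deaths$death_date + 5,
      discharge_disposition = NA_character_
    ))
  }
  classify_mortality(cohort, deaths, visits)$call
}

# shared simulations, built once per test run
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function(key, config) {
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_ehr_bundle(config)
  }
  .sim_cache[[key]]
}

sim_small <- function() {
  cached_sim("small", sim_config(n_sites = 3, patients_per_site = 150, seed = 101))
}

sim_clean <- function() {
  cached_sim("clean", sim_config(
    n_sites = 3, patients_per_site = 120, seed = 202,
    p_reversed = 0, p_missing_sex = 0, p_missing_age = 0
  ))
}
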