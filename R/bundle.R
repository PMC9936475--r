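#' Assemble an EHR bundle from its component tables
#'
#' An EHR bundle is the set of OMOP-lite tables describing one multi-site
#' extract: `person`, `visit_occurrence`, `drug_exposure`, `measurement`,
#' `condition_occurrence`, `death`, `concept`, `concept_ancestor` and `site`.
#' The constructor coerces columns to the dialect's types (all dates at day
#' resolution, missing values encoded by `NA`, never sentinels) and checks
#' that the required columns are present.  Invariant violations in the *data*
#' (reversed intervals, missing demographics, broken references) are never
#' dropped here; they are surfaced by [validate_bundle()] and each analysis
#' stage applies its own documented drop rules.
#'
#' @param tables Named list with one tibble per dialect table.
#' @return An object of class `ehr_bundle`: a named list of tibbles with a
#'   `dialect_version` attribute.
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
ehr_bundle <- function(tables) {
  schema <- ehr_schema()
  missing <- setdiff(names(schema), names(tables))
  if (length(missing) > 0) {
    abort(paste0("missing required table(s): ", paste(missing, collapse = ", ")))
  }
  out <- imap(schema, function(def, tab) {
    x <- as_tibble(tables[[tab]])
    missing_cols <- setdiff(names(def$cols), names(x))
    if (length(missing_cols) > 0) {
      abort(sprintf(
        "table '%s' lacks required column(s): %s",
        tab, paste(missing_cols, collapse = ", ")
      ))
    }
    extra <- setdiff(names(x), names(def$cols))
    if (length(extra) > 0) {
      warn(sprintf(
        "table '%s': ignoring unknown column(s): %s",
        tab, paste(extra, collapse = ", ")
      ))
      x <- x[, names(def$cols)]
    }
    for (col in names(def$cols)) {
      x[[col]] <- switch(def$cols[[col]],
        character = as.character(x[[col]]),
        integer   = as.integer(x[[col]]),
        double    = as.double(x[[col]]),
        # timestamps are truncated: the dialect is day-resolution
        date      = as.Date(x[[col]])
      )
    }
    x[, names(def$cols)]
  })
  structure(out, class = "ehr_bundle", dialect_version = "0.1")
}

#' @export
print.ehr_bundle <- function(x, ...) {
  cat("<ehr_bundle> dialect", attr(x, "dialect_version"), "\n")
  for (tab in names(x)) {
    cat(sprintf("  %-20s %7d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Read an EHR bundle from a directory of table files
#'
#' Expects one file per dialect table (`person.csv`, `visit_occurrence.csv`,
#' ... or the `.parquet` mirror).  A missing required table is a fatal error;
#' unknown columns are dropped with a warning.  All invariants are checked on
#' load and the itemized violation report is attached as the `"validation"`
#' attribute — violating rows (e.g. drug exposures with end before start) are
#' retained, never silently dropped.
#'
#' @param path Directory containing the table files.
#' @param format `"csv"` (RFC-4180, UTF-8, ISO-8601 dates) or `"parquet"`.
#' @return An `ehr_bundle` with a `validation` attribute (see
#'   [validate_bundle()]).
#' @export
read_bundle <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  ext <- paste0(".", format)
  files <- file.path(path, paste0(ehr_tables(), ext))
  present <- file.exists(files)
  if (!all(present)) {
    abort(paste0(
      "missing required table file(s): ",
      paste(basename(files[!present]), collapse = ", ")
    ))
  }
  tables <- lapply(seq_along(files), function(i) {
    if (format == "csv") {
      readr::read_csv(
        files[i],
        col_types = readr_spec(ehr_tables()[i]), na = "",
        progress = FALSE
      )
    } else {
      rlang::check_installed("arrow", reason = "to read Parquet bundles")
      arrow::read_parquet(files[i])
    }
  })
  names(tables) <- ehr_tables()
  bundle <- ehr_bundle(tables)
  attr(bundle, "validation") <- validate_bundle(bundle)
  bundle
}

readr_spec <- function(tab) {
  cols <- ehr_schema()[[tab]]$cols
  spec <- lapply(unname(cols), function(tp) {
    switch(tp,
      character = readr::col_character(),
      integer   = readr::col_integer(),
      double    = readr::col_double(),
      date      = readr::col_date(format = "%Y-%m-%d")
    )
  })
  names(spec) <- names(cols)
  do.call(readr::cols, c(spec, .default = readr::col_character()))
}

#' Write an EHR bundle to a directory
#'
#' One file per table, named after the table.  CSV output is RFC-4180 UTF-8
#' with ISO-8601 dates and missing values written as empty fields; the
#' Parquet mirror carries an identical schema.  `write_bundle()` followed by
#' [read_bundle()] is the identity on row multisets for both formats.
#'
#' @inheritParams read_bundle
#' @param bundle An `ehr_bundle`.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  stopifnot(inherits(bundle, "ehr_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (tab in ehr_tables()) {
    file <- file.path(path, paste0(tab, ".", format))
    if (format == "csv") {
      readr::write_csv(bundle[[tab]], file, na = "", progress = FALSE)
    } else {
      rlang::check_installed("arrow", reason = "to write Parquet bundles")
      arrow::write_parquet(bundle[[tab]], file)
    }
  }
  invisible(path)
}

#' Itemize invariant violations in a bundle
#'
#' Pure reporting: the bundle is never mutated and violating rows are never
#' dropped.  Checks cover demographics (missing sex or birth year,
#' implausible birth year), duplicate person ids, reversed visit and drug
#' intervals, unresolvable concept ids, conflicting death records, and
#' referential integrity of rows to persons and persons to sites.
#'
#' @param bundle An `ehr_bundle`.
#' @return Tibble with columns `table`, `check`, `site_id`, `n` — one row per
#'   (table, check, site) with a positive violation count; zero rows for a
#'   clean bundle.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "ehr_bundle"))
  per_site <- function(tbl, mask, table, check) {
    tbl |>
      filter(mask) |>
      count(site_id, name = "n") |>
      mutate(table = table, check = check, .before = 1)
  }
  p <- bundle$person
  v <- bundle$visit_occurrence
  d <- bundle$drug_exposure
  co <- bundle$condition_occurrence
  de <- bundle$death
  known_concepts <- bundle$concept$concept_id
  known_persons <- p$person_id
  known_sites <- bundle$site$site_id

  dup_person <- p$person_id %in% p$person_id[duplicated(p$person_id)]
  multi_death <- de$person_id %in% de$person_id[duplicated(de$person_id)]

  out <- bind_rows(
    per_site(p, is.na(p$sex) | is.na(p$birth_year),
             "person", "demographics_missing"),
    per_site(p, !is.na(p$birth_year) & (p$birth_year < 1900 | p$birth_year > 2021),
             "person", "birth_year_implausible"),
    per_site(p, dup_person, "person", "person_id_duplicate"),
    per_site(p, !(p$site_id %in% known_sites), "person", "unknown_site"),
    per_site(v, !is.na(v$end_date) & v$end_date < v$start_date,
             "visit_occurrence", "interval_reversed"),
    per_site(d, !is.na(d$end_date) & d$end_date < d$start_date,
             "drug_exposure", "interval_reversed"),
    per_site(d, !(d$concept_id %in% known_concepts),
             "drug_exposure", "concept_unresolvable"),
    per_site(co, !(co$concept_id %in% known_concepts),
             "condition_occurrence", "concept_unresolvable"),
    per_site(de, multi_death, "death", "multiple_death_records"),
    per_site(v, !(v$person_id %in% known_persons),
             "visit_occurrence", "unknown_person"),
    per_site(d, !(d$person_id %in% known_persons),
             "drug_exposure", "unknown_person"),
    per_site(bundle$measurement,
             !(bundle$measurement$person_id %in% known_persons),
             "measurement", "unknown_person"),
    per_site(co, !(co$person_id %in% known_persons),
             "condition_occurrence", "unknown_person"),
    per_site(de, !(de$person_id %in% known_persons), "death", "unknown_person")
  )
  if (nrow(out) == 0) {
    out <- tibble(
      table = character(), check = character(),
      site_id = character(), n = integer()
    )
  }
  arrange(out, table, check, site_id)
}
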