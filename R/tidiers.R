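# broom-style accessors for the package's fitted/derived objects

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a drug-era reconstruction
#'
#' @param x A [build_drug_eras()] result.
#' @param ... Unused.
#' @return The `eras` tibble.
#' @export
tidy.drug_eras <- function(x, ...) x$eras

#' One-row summary of a drug-era reconstruction
#'
#' @param x A [build_drug_eras()] result.
#' @param ... Unused.
#' @return Tibble with era counts, total exposure days and the cleaning-log
#'   counts.
#' @export
glance.drug_eras <- function(x, ...) {
  log <- setNames(as.list(x$log$n), x$log$action)
  tibble(
    n_eras = nrow(x$eras),
    n_patients = n_distinct(x$eras$person_id),
    total_exposure_days = sum(x$eras$exposure_days),
    n_single_day = sum(x$eras$exposure_days == 1L),
    discarded_reversed = log$discarded_reversed,
    open_as_single_day = log$open_as_single_day,
    duplicates_removed = log$duplicates_removed,
    gap_days = x$gap_days
  )
}

#' Tidy a site clustering
#'
#' @param x A [cluster_sites()] result.
#' @param ... Unused.
#' @return The `labels` tibble (`site_id`, `cluster`, `mean_completeness`,
#'   `retained`).
#' @export
tidy.site_clusters <- function(x, ...) x$labels

#' One-row summary of a site clustering
#'
#' @param x A [cluster_sites()] result.
#' @param ... Unused.
#' @return Tibble with `k`, site counts and the retained cluster's mean
#'   completeness.
#' @export
glance.site_clusters <- function(x, ...) {
  tibble(
    k = x$k,
    n_sites = nrow(x$labels),
    n_retained = sum(x$labels$retained),
    mean_completeness_retained =
      mean(x$labels$mean_completeness[x$labels$retained])
  )
}

#' Tidy a disposition audit
#'
#' @param x A [disposition_audit()] result.
#' @param ... Unused.
#' @return The pooled top-k disposition table.
#' @export
tidy.disposition_audit <- function(x, ...) x$top

#' One-row summary of a disposition audit
#'
#' @param x A [disposition_audit()] result.
#' @param ... Unused.
#' @return Tibble with site counts and overall availability.
#' @export
glance.disposition_audit <- function(x, ...) {
  tibble(
    n_sites = nrow(x$by_site),
    n_sites_no_reporting = sum(x$by_site$no_reporting),
    overall_availability =
      100 * sum(x$by_site$n_reported) / sum(x$by_site$n_visits)
  )
}
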