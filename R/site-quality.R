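#' Per-site completeness of key measurements
#'
#' For every contributing site and measurement variable, the percentage of
#' included cohort patients with at least one recorded value during their
#' hospitalization (macrovisit days, closed interval).
#'
#' @param bundle An [ehr_bundle()].
#' @param cohort Output of [select_cohort()]; only `included` rows count.
#' @param variables Measurement variables to profile.
#' @return Tibble `site_id`, `variable`, `n_patients`, `n_with_value`,
#'   `completeness` (0-100).
#' @export
completeness_matrix <- function(bundle, cohort,
                                variables = measurement_variables()) {
  pats <- cohort |>
    filter(included) |>
    select(person_id, site_id, admission_date, discharge_date)
  hits <- pats |>
    inner_join(bundle$measurement |> select(person_id, variable, date),
               by = "person_id", relationship = "many-to-many") |>
    filter(variable %in% variables,
           date >= admission_date, date <= discharge_date) |>
    distinct(person_id, variable) |>
    mutate(has = TRUE)
  crossing(pats |> select(person_id, site_id), variable = variables) |>
    left_join(hits, by = c("person_id", "variable")) |>
    group_by(site_id, variable) |>
    summarise(
      n_patients = n(),
      n_with_value = sum(!is.na(has)),
      completeness = 100 * n_with_value / n_patients,
      .groups = "drop"
    )
}

#' Temporal missingness by site and pandemic month
#'
#' Fraction of that month's cohort patients (by calendar month of admission)
#' with no value of each variable during their stay.  Complements
#' [completeness_matrix()]: for a single month, missingness = 1 -
#' completeness/100.
#'
#' @inheritParams completeness_matrix
#' @return Tibble `site_id`, `month` ("YYYY-MM"), `variable`, `n_patients`,
#'   `frac_missing` (0-1).  Site-months with no cohort patients are absent,
#'   not zero.
#' @export
temporal_missingness <- function(bundle, cohort,
                                 variables = measurement_variables()) {
  pats <- cohort |>
    filter(included) |>
    mutate(month = month_label(admission_date)) |>
    select(person_id, site_id, month, admission_date, discharge_date)
  hits <- pats |>
    inner_join(bundle$measurement |> select(person_id, variable, date),
               by = "person_id", relationship = "many-to-many") |>
    filter(variable %in% variables,
           date >= admission_date, date <= discharge_date) |>
    distinct(person_id, variable) |>
    mutate(has = TRUE)
  crossing(pats |> select(person_id, site_id, month), variable = variables) |>
    left_join(hits, by = c("person_id", "variable")) |>
    group_by(site_id, month, variable) |>
    summarise(
      n_patients = n(),
      frac_missing = mean(is.na(has)),
      .groups = "drop"
    )
}

#' Hierarchically cluster sites on their completeness profiles
#'
#' Agglomerative clustering of sites on their completeness vectors
#' (Euclidean distance, average linkage by default — the source analysis
#' does not state its choices, so both are configurable).  Cutting at `k`
#' clusters, the retained cluster is the one with the higher mean
#' completeness; with `k = 2` this reproduces "keep the first top-level
#' cluster" screening.
#'
#' @param completeness Output of [completeness_matrix()].
#' @param k Number of clusters to cut into.
#' @param dist_method,linkage Passed to [stats::dist()] / [stats::hclust()].
#' @return An object of class `site_clusters`: list with the `hclust` tree,
#'   a `labels` tibble (`site_id`, `cluster`, `mean_completeness`,
#'   `retained`) and `k`.  A single site yields one trivial cluster.
#' @export
cluster_sites <- function(completeness, k = 2, dist_method = "euclidean",
                          linkage = "average") {
  wide <- completeness |>
    select(site_id, variable, completeness) |>
    arrange(site_id, variable) |>
    pivot_wider(names_from = variable, values_from = completeness)
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$site_id
  if (nrow(mat) < 2) {
    labels <- tibble(
      site_id = wide$site_id, cluster = 1L,
      mean_completeness = rowMeans(mat), retained = TRUE
    )
    return(structure(list(tree = NULL, labels = labels, k = 1L),
                     class = "site_clusters"))
  }
  tree <- hclust(dist(mat, method = dist_method), method = linkage)
  k <- min(k, nrow(mat))
  cl <- cutree(tree, k = k)
  labels <- tibble(
    site_id = rownames(mat),
    cluster = unname(cl),
    mean_completeness = rowMeans(mat)
  )
  best <- labels |>
    group_by(cluster) |>
    summarise(m = mean(mean_completeness)) |>
    slice_max(.data$m, n = 1, with_ties = FALSE) |>
    pull(cluster)
  labels$retained <- labels$cluster == best
  structure(list(tree = tree, labels = labels, k = k),
            class = "site_clusters")
}

#' @export
print.site_clusters <- function(x, ...) {
  cat("<site_clusters> k =", x$k, "-", sum(x$labels$retained),
      "of", nrow(x$labels), "sites in the retained cluster\n")
  invisible(x)
}

#' Default thresholds for the site exclusion rules
#'
#' @param vitals_missing_max Maximum tolerated mean missingness across the
#'   key vitals (0.70: sites missing over 70% are excluded).
#' @param sd_mult How many standard deviations above the global mean the
#'   two-SD rules tolerate.
#' @param max_shift_days Maximum tolerated per-site date shift (one week).
#' @return Named list of thresholds.
#' @export
site_thresholds <- function(vitals_missing_max = 0.70, sd_mult = 2,
                            max_shift_days = 7) {
  stopifnot(vitals_missing_max > 0, sd_mult > 0, max_shift_days > 0)
  list(vitals_missing_max = vitals_missing_max, sd_mult = sd_mult,
       max_shift_days = max_shift_days)
}

#' Apply the site exclusion rules
#'
#' A site is excluded iff any rule fires:
#' \describe{
#'   \item{vitals_below_threshold}{mean missingness across the key vitals
#'     above `vitals_missing_max` (default 70%).}
#'   \item{missing_gt_2sd}{mean missing proportion (over `variables`) above
#'     the global mean by more than `sd_mult` population SDs.}
#'   \item{temporal_var_gt_2sd}{temporal variance — the variance across
#'     pandemic months of the site's monthly missing fraction, averaged over
#'     variables — above the global mean temporal variance by more than
#'     `sd_mult` population SDs.}
#'   \item{date_shift_gt_7d}{site metadata records a date shift beyond
#'     `max_shift_days`.}
#'   \item{cluster_dropout}{site falls outside the retained completeness
#'     cluster (only when `clusters` is supplied).}
#' }
#' Global moments are computed once over all sites before any exclusion (no
#' iterative re-screening).  When all sites are identical the SDs are zero
#' and the strict inequalities fire for no one.
#'
#' @param completeness Output of [completeness_matrix()].
#' @param temporal Output of [temporal_missingness()].
#' @param site_meta The bundle's `site` table.
#' @param thresholds See [site_thresholds()].
#' @param vitals Key vitals for the 70% rule.
#' @param clusters Optional [cluster_sites()] result.
#' @return Tibble, one row per site: `site_id`, `mean_missing`,
#'   `vitals_missing`, `temporal_variance`, `max_date_shift_days`,
#'   `excluded`, `reasons` (";"-separated, empty when retained).
#'   `excluded` is `TRUE` iff `reasons` is non-empty.
#' @export
apply_exclusion_rules <- function(completeness, temporal, site_meta,
                                  thresholds = site_thresholds(),
                                  vitals = key_vitals(),
                                  clusters = NULL) {
  per_site <- completeness |>
    group_by(site_id) |>
    summarise(
      mean_missing = mean(1 - completeness / 100),
      vitals_missing = mean((1 - completeness / 100)[variable %in% vitals]),
      .groups = "drop"
    )
  tvar <- temporal |>
    group_by(site_id, variable) |>
    summarise(v = if (n() > 1) var(.data$frac_missing) else 0, .groups = "drop") |>
    group_by(site_id) |>
    summarise(temporal_variance = mean(.data$v), .groups = "drop")
  prof <- per_site |>
    left_join(tvar, by = "site_id") |>
    left_join(site_meta |> select(site_id, max_date_shift_days),
              by = "site_id") |>
    mutate(temporal_variance = coalesce(temporal_variance, 0))

  g_mean <- mean(prof$mean_missing)
  g_sd <- pop_sd(prof$mean_missing)
  tv_mean <- mean(prof$temporal_variance)
  tv_sd <- pop_sd(prof$temporal_variance)

  reason_tbl <- tibble(
    site_id = prof$site_id,
    vitals_below_threshold = prof$vitals_missing > thresholds$vitals_missing_max,
    missing_gt_2sd = prof$mean_missing > g_mean + thresholds$sd_mult * g_sd,
    temporal_var_gt_2sd =
      prof$temporal_variance > tv_mean + thresholds$sd_mult * tv_sd,
    date_shift_gt_7d =
      coalesce(prof$max_date_shift_days, 0L) > thresholds$max_shift_days,
    cluster_dropout = if (is.null(clusters)) FALSE else {
      !prof$site_id %in% clusters$labels$site_id[clusters$labels$retained]
    }
  )
  reasons <- apply(as.matrix(reason_tbl[, -1]), 1, function(r) {
    paste(names(r)[r], collapse = ";")
  })
  prof |>
    mutate(reasons = reasons, excluded = reasons != "") |>
    arrange(site_id)
}

#' Per-patient missingness and value summary, one row per variable
#'
#' For each variable: how many included patients have any value in the
#' chosen window, the missing percentage, and the median (IQR) of each
#' patient's representative (first-in-window) value.  `whole_visit` uses the
#' full macrovisit; `admission_2d` restricts to the first
#' `1 + admission_window_days` days of the stay.
#'
#' @inheritParams completeness_matrix
#' @param window `"whole_visit"` or `"admission_2d"`.
#' @param admission_window_days Days after admission included under
#'   `admission_2d`.
#' @return Tibble `variable`, `n_nonmissing`, `n_missing`, `pct_missing`,
#'   `median`, `q1`, `q3`.
#' @export
patient_missingness_table <- function(bundle, cohort,
                                      variables = measurement_variables(),
                                      window = c("whole_visit", "admission_2d"),
                                      admission_window_days = 2) {
  window <- match.arg(window)
  pats <- cohort |>
    filter(included) |>
    mutate(
      win_end = if (window == "whole_visit") discharge_date else {
        pmin(discharge_date, admission_date + admission_window_days)
      }
    ) |>
    select(person_id, admission_date, win_end)
  n_total <- nrow(pats)
  firsts <- pats |>
    inner_join(bundle$measurement |> select(person_id, variable, value, date),
               by = "person_id", relationship = "many-to-many") |>
    filter(variable %in% variables, date >= admission_date, date <= win_end) |>
    arrange(person_id, variable, date) |>
    distinct(person_id, variable, .keep_all = TRUE)
  firsts |>
    group_by(variable) |>
    summarise(
      n_nonmissing = n(),
      median = median(value), q1 = quantile(value, 0.25, names = FALSE),
      q3 = quantile(value, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    right_join(tibble(variable = variables), by = "variable") |>
    mutate(
      n_nonmissing = coalesce(n_nonmissing, 0L),
      n_missing = n_total - n_nonmissing,
      pct_missing = if (n_total > 0) 100 * n_missing / n_total else NA_real_
    ) |>
    select(variable, n_nonmissing, n_missing, pct_missing, median, q1, q3) |>
    arrange(match(variable, variables))
}
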