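# ggplot2 views of the main result types; all headless-safe.

#' Heatmap of per-site completeness
#'
#' @param completeness Output of [completeness_matrix()].
#' @return A ggplot.
#' @export
plot_completeness <- function(completeness) {
  ggplot2::ggplot(completeness,
                  ggplot2::aes(.data$variable, .data$site_id,
                               fill = .data$completeness)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% patients\nwith value") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Patients with at least one value, by site") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of temporal missingness for one variable
#'
#' @param temporal Output of [temporal_missingness()].
#' @param variable Variable to show (default: averaged over variables).
#' @return A ggplot.
#' @export
plot_temporal_missingness <- function(temporal, variable = NULL) {
  if (!is.null(variable)) {
    temporal <- temporal |> filter(.data$variable == !!variable)
  }
  agg <- temporal |>
    group_by(site_id, month) |>
    summarise(frac_missing = mean(.data$frac_missing), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(.data$month, .data$site_id,
                                    fill = .data$frac_missing)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "fraction\nmissing") +
    ggplot2::labs(x = "pandemic month", y = NULL,
                  title = "Missingness by site and month") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Histogram of treatment durations
#'
#' @param durations Output of [duration_distribution()].
#' @return A ggplot.
#' @export
plot_duration_distribution <- function(durations) {
  ggplot2::ggplot(durations, ggplot2::aes(.data$duration_days, .data$prop)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "treatment duration (days)", y = "proportion of patients",
                  title = "First drug-era duration") +
    ggplot2::theme_minimal()
}

#' Histogram of death-date offsets from visit end
#'
#' @param deltas Output of [death_delta_distribution()].
#' @return A ggplot.
#' @export
plot_death_deltas <- function(deltas) {
  ggplot2::ggplot(deltas, ggplot2::aes(.data$delta_days, .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "death date - visit end date (days)", y = "patients",
                  title = "Death-date offsets") +
    ggplot2::theme_minimal()
}

#' Heatmap of the no-history fraction by site and month
#'
#' @param heatmap Output of [no_history_heatmap()].
#' @return A ggplot.
#' @export
plot_no_history <- function(heatmap) {
  ggplot2::ggplot(heatmap, ggplot2::aes(.data$month, .data$site_id,
                                        fill = .data$frac)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "fraction\nno history") +
    ggplot2::labs(x = "pandemic month", y = NULL,
                  title = "Patients with no prior history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Love plot of standardized mean differences
#'
#' @param smds Output of [smd_table()].
#' @param negligible_at Reference line for the negligible-difference
#'   convention.
#' @return A ggplot.
#' @export
plot_smd <- function(smds, negligible_at = 0.1) {
  smds <- smds |> mutate(variable = factor(variable, rev(variable)))
  ggplot2::ggplot(smds, ggplot2::aes(.data$abs_smd, .data$variable)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = negligible_at, linetype = "dashed") +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL,
                  title = "Covariate balance by prior history") +
    ggplot2::theme_minimal()
}

#' Dendrogram of the site completeness clustering
#'
#' @param x A [cluster_sites()] result.
#' @param ... Passed to [plot()].
#' @export
plot.site_clusters <- function(x, ...) {
  if (is.null(x$tree)) {
    abort("a single site has no dendrogram to plot")
  }
  plot(x$tree, xlab = "site", sub = "", main = "Site completeness clustering",
       ...)
  invisible(x)
}
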