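# internal helpers shared across modules

# Consolidate closed day-resolution date intervals per person.
#
# Two intervals belong to the same run when they overlap or the gap of empty
# days between them is <= gap_days (gap 0 means abutting intervals merge).
# Adds an integer column .grp identifying the run within each person.
consolidate_intervals <- function(tbl, gap_days, keys = "person_id") {
  stopifnot(gap_days >= 0)
  tbl |>
    mutate(.s = as.integer(.data$start_date), .e = as.integer(.data$end_date)) |>
    arrange(across(all_of(keys)), .data$.s, .data$.e) |>
    group_by(across(all_of(keys))) |>
    mutate(
      .pm = lag(cummax(.data$.e)),
      .new = is.na(.data$.pm) | .data$.s > .data$.pm + gap_days + 1L,
      .grp = cumsum(.data$.new)
    ) |>
    ungroup() |>
    select(-".pm", -".new")
}

# floor a Date to the first of its calendar month, formatted "YYYY-MM"
month_label <- function(x) format(x, "%Y-%m")

# year component of a Date as integer
date_year <- function(x) as.integer(format(x, "%Y"))

# population standard deviation (denominator n)
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# sample() without the scalar-x surprise
sample_vec <- function(x, size, replace = TRUE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# format "median (q1, q3)" with a fixed number of digits
fmt_median_iqr <- function(x, digits = 1) {
  if (all(is.na(x))) return(NA_character_)
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f (%.*f, %.*f)", digits, q[1], digits, q[2], digits, q[3])
}

# format "n (pct%)" with small-cell suppression
fmt_n_pct <- function(n, total, suppress_below = 0) {
  pct <- ifelse(total > 0, 100 * n / total, NA_real_)
  out <- sprintf("%d (%.1f%%)", n, pct)
  if (suppress_below > 0) {
    out[n > 0 & n < suppress_below] <- paste0("<", suppress_below)
  }
  out
}

# min of a date vector that is NA (not a warning) on empty input
min_date <- function(x) {
  if (length(x) == 0) return(as.Date(NA))
  min(x)
}
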