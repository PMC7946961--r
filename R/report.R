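# Aggregation of instantaneous power into monthly/yearly mean-power tables,
# threshold flags, weekday/weekend profile combinations and cell-comparison
# ratios.

#' Mean power over calendar periods
#'
#' Mean output power normalized to the *full elapsed time* of the period —
#' nights and unexposed hours included — as energy (trapezoid in time over
#' the record cadence) divided by the full period duration. Months whose
#' record coverage falls below the coverage threshold are flagged missing
#' (`NA`).
#'
#' @param ps A `power_series` (one or more profiles).
#' @param coverage_threshold Minimum fraction of expected records for a
#'   month to count (default 0.5).
#' @return A tibble `profile`, `period` (`"1"`..`"12"`, `"Full year"`),
#'   `mean_uW`.
#' @export
mean_power <- function(ps, coverage_threshold = 0.5) {
  stopifnot(inherits(ps, "power_series"))
  one <- ps[ps$profile == ps$profile[1], ]
  step <- median(as.numeric(diff(one$timestamp), units = "mins"))
  yr <- as.integer(format(one$timestamp[1], "%Y"))

  cov <- dplyr::count(
    dplyr::mutate(one, month = as.integer(format(.data$timestamp, "%m"))),
    .data$month
  )
  cov$expected <- vapply(cov$month, function(m) days_in_month(yr, m) * 1440 / step,
                         numeric(1))
  cov$missing <- cov$n / cov$expected < coverage_threshold

  year_seconds <- as.numeric(
    as.POSIXct(sprintf("%d-01-01", yr + 1), tz = "UTC") -
      as.POSIXct(sprintf("%d-01-01", yr), tz = "UTC"), units = "secs")

  purrr::map_dfr(unique(ps$profile), function(p) {
    d <- ps[ps$profile == p, ]
    d$month <- as.integer(format(d$timestamp, "%m"))
    monthly <- purrr::map_dbl(1:12, function(m) {
      rows <- which(d$month == m)
      info <- cov[cov$month == m, ]
      if (length(rows) < 2 || nrow(info) == 0 || info$missing) return(NA_real_)
      tsec <- as.numeric(d$timestamp[rows]) # seconds
      energy <- trapz(tsec, d$pout_w[rows]) # joules
      msec <- days_in_month(yr, m) * 86400
      energy / msec * 1e6
    })
    energy_year <- trapz(as.numeric(d$timestamp), d$pout_w)
    tibble(profile = p, period = c(as.character(1:12), "Full year"),
           mean_uW = c(monthly, energy_year / year_seconds * 1e6))
  })
}

#' Monthly/yearly mean-power summary table
#'
#' Wide table with rows months 1-12 plus "Full year" and one column per
#' profile (mean power in microwatts; `NA` marks months excluded by the
#' coverage rule). The yearly row is total harvested energy over the full
#' year duration, not the mean of the monthly means.
#'
#' @inheritParams mean_power
#' @return A `power_summary` tibble.
#' @export
power_summary <- function(ps, coverage_threshold = 0.5) {
  long <- mean_power(ps, coverage_threshold)
  out <- tidyr::pivot_wider(long, names_from = "profile", values_from = "mean_uW")
  out$period <- factor(out$period, levels = c(as.character(1:12), "Full year"))
  out <- out[order(out$period), ]
  out$period <- as.character(out$period)
  attr(out, "cell") <- attr(ps, "cell")
  attr(out, "skin") <- attr(ps, "skin")
  class(out) <- c("power_summary", class(out))
  out
}

#' Combine weekday and weekend profiles into one yearly mean
#'
#' All profile means are normalized to full elapsed time, so a routine that
#' follows a weekday profile plus, on `n_active` of the year's `n_weekend`
#' weekend days, the active-weekend profile (passive-weekend otherwise) has
#' combined yearly mean
#' `weekday + (n_active * active + (n_weekend - n_active) * passive) / n_weekend`.
#'
#' @param weekday_mean,active_mean,passive_mean Yearly means, microwatts.
#' @param n_active Active weekend days per year.
#' @param n_weekend Total weekend days per year (e.g. 104 in 2015).
#' @return Combined yearly mean, microwatts.
#' @examples
#' mix_weekend(48.87, 102.61, 1.08, 12, 104)
#' @export
mix_weekend <- function(weekday_mean, active_mean, passive_mean,
                        n_active, n_weekend) {
  if (n_weekend <= 0) {
    stop_subsolar("`n_weekend` must be positive.", "subsolar_parameter_error")
  }
  if (n_active < 0 || n_active > n_weekend) {
    stop_subsolar("need 0 <= n_active <= n_weekend.", "subsolar_parameter_error")
  }
  weekday_mean +
    (n_active * active_mean + (n_weekend - n_active) * passive_mean) / n_weekend
}

#' Pacemaker-threshold flags for a summary table
#'
#' Flags every cell of the table against a power requirement (default
#' 10 microwatts, the consumption of a modern single-chamber cardiac
#' pacemaker). A mean exactly at the threshold passes (`>=` convention).
#'
#' @param table A [power_summary()].
#' @param threshold Microwatts (default 10).
#' @return A tibble `period`, `profile`, `mean_uW`, `status`
#'   (`"pass"`/`"fail"`/`"missing"`).
#' @export
threshold_report <- function(table, threshold = 10) {
  long <- tidyr::pivot_longer(as_tibble(table), -"period",
                              names_to = "profile", values_to = "mean_uW")
  long$status <- dplyr::case_when(
    is.na(long$mean_uW) ~ "missing",
    long$mean_uW >= threshold ~ "pass",
    TRUE ~ "fail"
  )
  long
}

#' Ratio of yearly means between two summary tables
#'
#' Per-profile ratio of the "Full year" rows (e.g. a candidate cell vs a
#' reference cell under the same skin), reported at 2 decimals as in
#' published comparison tables. A zero or missing denominator yields `NA`.
#'
#' @param numerator,denominator [power_summary()] tables with matching
#'   profile columns.
#' @return A tibble `profile`, `ratio` (2 decimals), `ratio_exact`.
#' @export
ratio_table <- function(numerator, denominator) {
  profs <- setdiff(names(numerator), "period")
  if (!setequal(profs, setdiff(names(denominator), "period"))) {
    stop_subsolar("summary tables have different profile columns.",
                  "subsolar_alignment_error")
  }
  ny <- numerator[numerator$period == "Full year", profs, drop = FALSE]
  dy <- denominator[denominator$period == "Full year", profs, drop = FALSE]
  r <- purrr::map_dbl(profs, function(p) {
    den <- dy[[p]]
    if (is.na(den) || den == 0) NA_real_ else ny[[p]] / den
  })
  tibble(profile = profs, ratio = round(r, 2), ratio_exact = r)
}

#' Write a summary table CSV
#'
#' Months 1-12 plus "Full year" rows, profile columns in library order,
#' microwatts at 2 decimals; missing months serialize as empty cells.
#'
#' @param table A [power_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path) {
  df <- as.data.frame(table)
  for (p in setdiff(names(df), "period")) {
    df[[p]] <- ifelse(is.na(df[[p]]), "", sprintf("%.2f", df[[p]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a summary table CSV written by [write_summary()]
#' @param path CSV path.
#' @return A `power_summary` tibble.
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  out <- as_tibble(df)
  for (p in setdiff(names(out), "period")) {
    out[[p]] <- suppressWarnings(as.numeric(out[[p]]))
  }
  class(out) <- c("power_summary", class(out))
  out
}
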