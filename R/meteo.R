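# Ground radiation series: generic CSV reader, a BSRN station-to-archive
# subset reader, and a seedable synthetic-weather generator.

new_radiation_series <- function(records, meta) {
  out <- as_tibble(records)
  attr(out, "meta") <- meta
  class(out) <- c("radiation_series", class(out))
  out
}

#' @export
print.radiation_series <- function(x, ...) {
  m <- series_meta(x)
  cat(sprintf("# Radiation series: station %s (lat %.2f, lon %.2f), %d records\n",
              m$station_id, m$latitude, m$longitude, nrow(x)))
  NextMethod()
}

#' Station metadata attached to a radiation series
#' @param series A `radiation_series`.
#' @return The [station_meta()] object.
#' @export
series_meta <- function(series) {
  attr(series, "meta")
}

validate_series_records <- function(records) {
  if (nrow(records) == 0) {
    stop_subsolar("no valid radiation records (empty input).", "subsolar_empty_input_error")
  }
  dup <- records$timestamp[duplicated(records$timestamp)]
  if (length(dup) > 0) {
    stop_subsolar(
      sprintf("duplicate timestamp in series: %s",
              format(dup[1], "%Y-%m-%d %H:%M:%S", tz = "UTC")),
      "subsolar_invariant_error"
    )
  }
  records[order(records$timestamp), ]
}

# Clamp nighttime sensor offsets; idempotent by construction.
clean_ghi <- function(x) pmax(x, 0)

#' Read a generic irradiance CSV
#'
#' Expects a header and rows of ISO-8601 UTC timestamp plus global horizontal
#' irradiance in W m^-2 (`timestamp,ghi_wm2[,direct_wm2,diffuse_wm2]`).
#' Negative irradiance values (nighttime thermal offsets of pyranometers) are
#' clamped to 0 so the cadence is preserved; rows whose irradiance is not
#' numeric are dropped and counted in the `n_dropped` attribute.
#'
#' @param path CSV file path.
#' @param meta [station_meta()] for the station the file belongs to.
#' @return A `radiation_series` tibble (`timestamp`, `ghi`, optional `direct`,
#'   `diffuse`), sorted by time.
#' @export
read_ghi_csv <- function(path, meta) {
  stopifnot(inherits(meta, "station_meta"))
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop_subsolar(sprintf("cannot read '%s': %s", path, conditionMessage(e)),
                                      "subsolar_format_error")
  )
  if (!all(c("timestamp", "ghi_wm2") %in% names(raw))) {
    stop_subsolar("unparsable header: need columns `timestamp` and `ghi_wm2`.",
                  "subsolar_format_error")
  }
  ts <- suppressWarnings(readr::parse_datetime(raw$timestamp))
  attr(ts, "tzone") <- "UTC"
  ghi <- suppressWarnings(as.numeric(raw$ghi_wm2))
  keep <- !is.na(ts) & !is.na(ghi)
  rec <- tibble(timestamp = ts[keep], ghi = clean_ghi(ghi[keep]))
  for (col in c("direct_wm2", "diffuse_wm2")) {
    if (col %in% names(raw)) {
      rec[[sub("_wm2$", "", col)]] <- suppressWarnings(as.numeric(raw[[col]][keep]))
    }
  }
  rec <- validate_series_records(rec)
  out <- new_radiation_series(rec, meta)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Write a radiation series as a generic irradiance CSV
#'
#' Emits the dialect read by [read_ghi_csv()], bit-reproducibly for a given
#' series.
#' @param series A `radiation_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ghi_csv <- function(series, path) {
  df <- data.frame(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    ghi_wm2 = sprintf("%.6g", series$ghi)
  )
  if ("direct" %in% names(series)) df$direct_wm2 <- sprintf("%.6g", series$direct)
  if ("diffuse" %in% names(series)) df$diffuse_wm2 <- sprintf("%.6g", series$diffuse)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BSRN station-to-archive subset (basic measurements)
#'
#' Supports one documented layout of the monthly station-to-archive ASCII
#' files: a `*C0001` block whose first data line holds `station_id month year`,
#' followed by a `*C0100` basic-measurements block with whitespace-separated
#' rows `day minute ghi [direct] [diffuse]` (day of month, minute of day,
#' W m^-2). Missing-value sentinels of the -999 family map to missing; records
#' whose global irradiance is missing are excluded from the cleaned series.
#' Everything else should be converted to the generic CSV dialect first.
#'
#' @param path File path.
#' @param meta Optional [station_meta()]; defaults to the station id from the
#'   file with zero coordinates (supply real coordinates for geometry work).
#' @return A `radiation_series`.
#' @export
read_bsrn_subset <- function(path, meta = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop_subsolar("empty BSRN file.", "subsolar_empty_input_error")
  }
  starts <- grep("^\\*[CU]", lines)
  if (length(starts) == 0 || !grepl("^\\*[CU]0001", lines[starts[1]])) {
    stop_subsolar(sprintf("unsupported BSRN dialect at line %d: expected a *C0001 header block.",
                          if (length(starts)) starts[1] else 1L),
                  "subsolar_dialect_error")
  }
  hdr <- strsplit(trimws(lines[starts[1] + 1]), "\\s+")[[1]]
  if (length(hdr) < 3) {
    stop_subsolar(sprintf("unsupported BSRN dialect at line %d: header needs `station month year`.",
                          starts[1] + 1L), "subsolar_dialect_error")
  }
  station <- hdr[1]; month <- as.integer(hdr[2]); year <- as.integer(hdr[3])
  basic <- grep("^\\*[CU]0100", lines)
  if (length(basic) == 0) {
    stop_subsolar("unsupported BSRN dialect: no *C0100 basic-measurements block.",
                  "subsolar_dialect_error")
  }
  block_end <- c(starts[starts > basic[1]], length(lines) + 1L)[1] - 1L
  rows <- lines[(basic[1] + 1L):block_end]
  parse_row <- function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(rows[i]), "\\s+")[[1]]))
    if (length(f) < 3 || anyNA(f[1:2])) {
      stop_subsolar(sprintf("unsupported BSRN dialect at line %d: expected `day minute ghi ...`.",
                            basic[1] + i), "subsolar_dialect_error")
    }
    f
  }
  fields <- lapply(seq_along(rows), parse_row)
  day <- vapply(fields, `[`, numeric(1), 1)
  minute <- vapply(fields, `[`, numeric(1), 2)
  val <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_real_, numeric(1))
  sentinel <- function(x) ifelse(x <= -998, NA_real_, x)
  ghi <- sentinel(val(3)); direct <- sentinel(val(4)); diffuse <- sentinel(val(5))
  ts <- as.POSIXct(sprintf("%04d-%02d-%02d", year, month, day), tz = "UTC") + minute * 60
  if (is.null(meta)) meta <- station_meta(station, 0, 0)
  n_missing <- sum(is.na(ghi))
  keep <- !is.na(ghi)
  rec <- validate_series_records(
    tibble(timestamp = ts[keep], ghi = clean_ghi(ghi[keep]),
           direct = direct[keep], diffuse = diffuse[keep])
  )
  out <- new_radiation_series(rec, meta)
  attr(out, "n_missing") <- n_missing
  out
}

#' Synthesize a BSRN-like radiation year
#'
#' Generates a minute-cadence global-horizontal-irradiance series from solar
#' geometry: `ghi(t) = E0 * cos(theta) * tau^AM * c(t)`, with `E0` the solar
#' constant (1361 W m^-2), `tau` a broadband clear-sky transmittance, `AM` the
#' secant air mass, and `c(t)` a seeded, temporally correlated cloud
#' attenuation in (0, 1]. The cloud process is a first-order autoregressive
#' Gaussian on the log scale, exponentiated and capped at 1 (lognormal-ish
#' multiplicative attenuation); `c == 1` everywhere when `cloud = NULL`.
#' `ghi` is exactly 0 whenever the sun is below the horizon.
#'
#' @param meta [station_meta()].
#' @param year Calendar year (1901-2099).
#' @param step Cadence in minutes, one of 1, 2 or 3 (BSRN cadence).
#' @param tau Broadband clear-sky transmittance at AM = 1 (default 0.75).
#' @param cloud `NULL` for clear sky, or a list with `mean_clearness` in
#'   (0, 1], `sd` (log-scale spread) and `corr_minutes` (autocorrelation time).
#' @param seed Integer seed; the same seed yields a bit-identical series.
#' @return A `radiation_series` covering the full year at `step` cadence.
#' @examples
#' eq <- station_meta("EQ0", 0, 0)
#' s <- synthesize_series(eq, 2015, step = 3, cloud = NULL, seed = 1)
#' max(s$ghi)
#' @export
synthesize_series <- function(meta, year, step = 3, tau = 0.75,
                              cloud = list(mean_clearness = 0.7, sd = 0.5,
                                           corr_minutes = 120),
                              seed = 1L) {
  stopifnot(inherits(meta, "station_meta"))
  if (!step %in% c(1, 2, 3)) {
    stop_subsolar("`step` must be 1, 2 or 3 minutes.", "subsolar_parameter_error")
  }
  if (!is.numeric(year) || year < 1901 || year > 2099) {
    stop_subsolar("`year` must lie in 1901-2099.", "subsolar_parameter_error")
  }
  t0 <- as.POSIXct(sprintf("%04d-01-01 00:00:00", year), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%04d-01-01 00:00:00", year + 1), tz = "UTC")
  ts <- seq(t0, t1 - 1, by = step * 60)
  sp <- solar_zenith(meta, ts)
  up <- sp$zenith < 90
  am <- ifelse(sp$zenith < 85, 1 / cos(pmin(sp$zenith, 85) * pi / 180), NA_real_)
  # near-horizon: extend with the AM at the cutoff so clear-sky ghi stays
  # continuous and tiny rather than undefined
  am[up & is.na(am)] <- 1 / cos(85 * pi / 180)
  clear <- ifelse(up, .const$solar_constant * cos(sp$zenith * pi / 180) * tau^am, 0)

  if (is.null(cloud)) {
    cfac <- rep(1, length(ts))
  } else {
    stopifnot(cloud$mean_clearness > 0, cloud$mean_clearness <= 1)
    rho <- exp(-step / cloud$corr_minutes)
    mu <- log(cloud$mean_clearness)
    cfac <- withr::with_seed(as.integer(seed), {
      n <- length(ts)
      eps <- rnorm(n)
      x <- numeric(n)
      x[1] <- mu + cloud$sd * eps[1]
      for (i in 2:n) x[i] <- mu + rho * (x[i - 1] - mu) + cloud$sd * sqrt(1 - rho^2) * eps[i]
      pmin(1, exp(x))
    })
  }
  rec <- tibble(timestamp = ts, ghi = clear * cfac)
  new_radiation_series(rec, meta)
}

#' Per-month record coverage of a radiation series
#'
#' Fraction of expected timestamps present in each calendar month at the
#' series' cadence (inferred as the median timestamp spacing). Months below
#' `threshold` are flagged missing and excluded from monthly means downstream,
#' mirroring the blank months of incomplete archive datasets.
#'
#' @param series A `radiation_series`.
#' @param threshold Minimum coverage fraction for a month to count (default 0.5).
#' @return A tibble `year`, `month`, `n`, `coverage`, `missing`.
#' @export
series_coverage <- function(series, threshold = 0.5) {
  step <- median(as.numeric(diff(series$timestamp), units = "mins"))
  dplyr::count(
    dplyr::mutate(series,
                  year = as.integer(format(.data$timestamp, "%Y")),
                  month = as.integer(format(.data$timestamp, "%m"))),
    .data$year, .data$month
  ) |>
    dplyr::mutate(
      expected = vapply(seq_along(.data$month), function(i) {
        days_in_month(.data$year[i], .data$month[i]) * 24 * 60 / step
      }, numeric(1)),
      coverage = pmin(1, .data$n / .data$expected),
      missing = .data$coverage < threshold
    ) |>
    dplyr::select("year", "month", "n", "coverage", "missing")
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%04d-01-01", year + 1)) else
    as.Date(sprintf("%04d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}
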