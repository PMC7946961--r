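#' Station metadata
#'
#' Describes a ground radiation station (or any point on Earth) used for the
#' solar-geometry and exposure calculations.
#'
#' @param station_id Short identifier.
#' @param latitude Degrees, positive north. Must lie in \[-90, 90\].
#' @param longitude Degrees, positive east. Must lie in \[-180, 180\].
#' @param elevation Metres above sea level (informational).
#'
#' @return A `station_meta` object (named list).
#' @examples
#' station_meta("PAY", 46.82, 6.94, 491)
#' @export
station_meta <- function(station_id, latitude, longitude, elevation = 0) {
  assert_scalar_number(latitude, "latitude")
  assert_scalar_number(longitude, "longitude")
  if (latitude < -90 || latitude > 90) {
    stop_subsolar("`latitude` must lie in [-90, 90] degrees.",
                  "subsolar_parameter_error")
  }
  if (longitude < -180 || longitude > 180) {
    stop_subsolar("`longitude` must lie in [-180, 180] degrees.",
                  "subsolar_parameter_error")
  }
  structure(
    list(station_id = as.character(station_id), latitude = latitude,
         longitude = longitude, elevation = elevation),
    class = "station_meta"
  )
}

#' @export
print.station_meta <- function(x, ...) {
  cat(sprintf("<station_meta> %s  lat %.4f  lon %.4f  elev %.0f m\n",
              x$station_id, x$latitude, x$longitude, x$elevation))
  invisible(x)
}

#' Solar position (zenith angle) for a place and UTC time
#'
#' Computes the sun's zenith angle, declination, equation of time and true
#' solar time with the NOAA low-precision algorithm (fractional-year Fourier
#' series for declination and the equation of time, then the hour angle from
#' true solar time). Accuracy is a few hundredths of a degree over 1901-2099,
#' ample against the ~1 degree granularity of exposure modelling.
#'
#' @param meta A [station_meta()].
#' @param t UTC instants (`POSIXct` or parseable character), any length.
#'
#' @return A tibble with one row per instant: `timestamp`, `zenith` (degrees,
#'   0 = sun overhead), `declination` (degrees), `equation_of_time` (minutes)
#'   and `true_solar_time` (minutes of the local solar day).
#' @examples
#' pay <- station_meta("PAY", 46.82, 6.94)
#' solar_zenith(pay, as.POSIXct("2015-06-21 11:34:00", tz = "UTC"))
#' @export
solar_zenith <- function(meta, t) {
  stopifnot(inherits(meta, "station_meta"))
  t <- as_utc(t)
  yr <- as.integer(format(t, "%Y"))
  if (any(yr < 1901 | yr > 2099)) {
    stop_subsolar("timestamps must fall within 1901-2099 (validity range of the approximation).",
                  "subsolar_parameter_error")
  }
  doy <- as.integer(format(t, "%j"))
  hh <- as.integer(format(t, "%H"))
  mm <- as.integer(format(t, "%M"))
  ss <- as.numeric(format(t, "%OS"))
  leap <- (yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0
  ndays <- ifelse(leap, 366, 365)

  # fractional year, radians
  g <- 2 * pi / ndays * (doy - 1 + (hh - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)

  time_offset <- eqtime + 4 * meta$longitude         # minutes (UTC reference)
  tst <- hh * 60 + mm + ss / 60 + time_offset        # true solar time, minutes
  ha <- (tst / 4) - 180                              # hour angle, degrees

  lat_r <- meta$latitude * pi / 180
  cosz <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha * pi / 180)
  cosz <- pmin(1, pmax(-1, cosz))
  tibble(
    timestamp = t,
    zenith = acos(cosz) * 180 / pi,
    declination = decl * 180 / pi,
    equation_of_time = eqtime,
    true_solar_time = tst %% 1440
  )
}

#' Relative atmospheric path length (air mass)
#'
#' Plane-parallel secant air mass, `AM = 1 / cos(theta)`: 1 with the sun at
#' zenith, increasing as the sun approaches the horizon. Beyond the cutoff
#' zenith angle (default 85 degrees) the secant diverges and the result is
#' flagged `NA` ("no direct sun"); the refraction-corrected near-horizon
#' formulas are deliberately not used because irradiance there is negligible.
#'
#' @param theta Zenith angle(s) in degrees, in \[0, 180).
#' @param cutoff Zenith angle above which air mass is flagged, degrees.
#'
#' @return A tibble with `theta`, `air_mass` (`NA` when flagged) and
#'   `no_direct_sun` (logical).
#' @examples
#' air_mass(c(0, 48, 60, 89))
#' @export
air_mass <- function(theta, cutoff = 85) {
  if (!is.numeric(theta) || any(!is.finite(theta))) {
    stop_subsolar("`theta` must be finite numeric degrees.", "subsolar_parameter_error")
  }
  if (any(theta < 0) || any(theta >= 180)) {
    stop_subsolar("`theta` must lie in [0, 180) degrees.", "subsolar_parameter_error")
  }
  flagged <- theta >= cutoff
  am <- ifelse(flagged, NA_real_, 1 / cos(theta * pi / 180))
  tibble(theta = theta, air_mass = am, no_direct_sun = flagged)
}
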