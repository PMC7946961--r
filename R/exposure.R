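# Daily solar-exposure time-slot profiles: who is outside when.

parse_hhmm <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) {
    stop_subsolar(sprintf("cannot parse clock time '%s' (expected HH:MM).", x[bad][1]),
                  "subsolar_format_error")
  }
  vapply(m, function(g) as.numeric(g[2]) * 60 + as.numeric(g[3]), numeric(1))
}

format_hhmm <- function(minutes) sprintf("%02d:%02d", minutes %/% 60, minutes %% 60)

#' Exposure profile library
#'
#' Validates a tibble of exposure slots: one row per slot with columns
#' `profile`, `day_class` (`"weekday"`, `"weekend"` or `"both"`), and local
#' clock times `start`, `end` (`HH:MM`). Within a profile and day class,
#' slots must satisfy `start < end` and must not overlap.
#'
#' @param slots Tibble/data frame of slots.
#' @return A `profile_library` tibble with minute-of-day columns attached.
#' @export
profile_library <- function(slots) {
  slots <- as_tibble(slots)
  need <- c("profile", "day_class", "start", "end")
  if (!all(need %in% names(slots))) {
    stop_subsolar("slots need columns profile, day_class, start, end.",
                  "subsolar_format_error")
  }
  if (!all(slots$day_class %in% c("weekday", "weekend", "both"))) {
    stop_subsolar("day_class must be weekday, weekend or both.",
                  "subsolar_validation_error")
  }
  slots$start_min <- parse_hhmm(slots$start)
  slots$end_min <- parse_hhmm(slots$end)
  bad <- slots$start_min >= slots$end_min
  if (any(bad)) {
    stop_subsolar(sprintf("profile '%s': slot %s-%s has end <= start.",
                          slots$profile[bad][1], slots$start[bad][1], slots$end[bad][1]),
                  "subsolar_validation_error")
  }
  for (p in unique(slots$profile)) {
    for (cls in c("weekday", "weekend")) {
      s <- slots[slots$profile == p & slots$day_class %in% c(cls, "both"), ]
      if (nrow(s) < 2) next
      s <- s[order(s$start_min), ]
      if (any(s$start_min[-1] < s$end_min[-nrow(s)])) {
        stop_subsolar(sprintf("profile '%s' has overlapping %s slots.", p, cls),
                      "subsolar_validation_error")
      }
    }
  }
  class(slots) <- c("profile_library", class(slots))
  slots
}

#' Profiles bundled with the package
#'
#' The seven canonical daily-routine profiles: five weekday routines
#' (workaholic commuting in the dark margins of the day, 10 min/day; office
#' worker whose only exposure is the commute, 30 min/day; office worker with
#' a 10-min midday walk to lunch; the same plus an evening hour of free time;
#' outside worker, 4.5 h/day) and two weekend routines (active weekend,
#' 4.5 h/day; passive weekend, 5 min/day). Slot clock times are documented
#' approximations — published sources fix only the daily totals — and can be
#' overridden with [load_profiles()].
#'
#' @return A `profile_library`.
#' @examples
#' default_profiles()
#' @export
default_profiles <- function() {
  load_profiles(system.file("extdata", "exposure_profiles.csv",
                            package = "subsolar", mustWork = TRUE))
}

#' Load an exposure-profile CSV
#'
#' CSV columns `profile,day_class,start,end` with `HH:MM` local clock times.
#' @param path CSV path.
#' @return A `profile_library`.
#' @export
load_profiles <- function(path) {
  profile_library(utils::read.csv(path, colClasses = "character"))
}

#' Write an exposure-profile CSV
#' @param profiles A `profile_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(
    data.frame(profile = profiles$profile, day_class = profiles$day_class,
               start = profiles$start, end = profiles$end),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Daily exposed minutes per profile and day class
#' @param profiles A `profile_library`.
#' @return Tibble `profile`, `day_class` (weekday/weekend), `minutes`.
#' @export
profile_daily_minutes <- function(profiles) {
  all_prof <- unique(profiles$profile)
  purrr::map_dfr(c("weekday", "weekend"), function(cls) {
    dplyr::filter(as_tibble(profiles), .data$day_class %in% c(cls, "both")) |>
      dplyr::group_by(.data$profile) |>
      dplyr::summarise(minutes = sum(.data$end_min - .data$start_min), .groups = "drop") |>
      dplyr::right_join(tibble(profile = all_prof), by = "profile") |>
      dplyr::mutate(minutes = dplyr::coalesce(.data$minutes, 0),
                    day_class = cls)
  }) |>
    dplyr::select("profile", "day_class", "minutes")
}

# minute of local civil day + weekend flag for UTC instants at a station
local_clock <- function(t, meta) {
  loc <- t + civil_offset_hours(meta$longitude) * 3600
  list(
    minute = as.integer(format(loc, "%H", tz = "UTC")) * 60 +
      as.integer(format(loc, "%M", tz = "UTC")),
    weekend = format(loc, "%u", tz = "UTC") %in% c("6", "7")
  )
}

#' Is the implant exposed at a given instant?
#'
#' True iff the local civil time (UTC + `round(longitude / 15)` hours, no
#' daylight saving) falls inside a slot of `profile` applicable to that
#' day's class (Saturday/Sunday = weekend). Slots are half-open
#' `[start, end)`.
#'
#' @param profiles A `profile_library`.
#' @param profile Profile name.
#' @param t UTC instants.
#' @param meta [station_meta()] (for the longitude-based civil-time offset).
#' @return Logical vector.
#' @export
is_exposed <- function(profiles, profile, t, meta) {
  t <- as_utc(t)
  s <- profiles[profiles$profile == profile, ]
  if (nrow(s) == 0) {
    stop_subsolar(sprintf("unknown profile '%s'.", profile), "subsolar_parameter_error")
  }
  lc <- local_clock(t, meta)
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(s))) {
    applies <- switch(s$day_class[i],
                      weekday = !lc$weekend,
                      weekend = lc$weekend,
                      both = rep(TRUE, length(t)))
    out <- out | (applies & lc$minute >= s$start_min[i] & lc$minute < s$end_min[i])
  }
  out
}
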