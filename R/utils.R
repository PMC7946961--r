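# Internal helpers shared across modules.

# Trapezoidal quadrature weights for an arbitrary strictly increasing grid.
# Integrating f on grid x is then sum(trapz_weights(x) * f).
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  dx <- diff(x)
  w[1] <- dx[1] / 2
  w[n] <- dx[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dx[-(n - 1)] + dx[-1]) / 2
  w
}

trapz <- function(x, y) pracma::trapz(x, y)

# Local civil time offset in hours used for exposure slots: UTC + round(lon/15).
# Deliberately timezone-database-free (reproducible; slot times are nominal).
civil_offset_hours <- function(longitude) {
  round(longitude / 15)
}

stop_subsolar <- function(msg, class) {
  rlang::abort(msg, class = c(class, "subsolar_error"))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_subsolar(sprintf("`%s` must be a single finite number.", name),
                  "subsolar_parameter_error")
  }
  invisible(x)
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  out <- as.POSIXct(x, tz = "UTC")
  if (anyNA(out)) {
    stop_subsolar("timestamps could not be parsed as UTC instants.",
                  "subsolar_format_error")
  }
  out
}
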