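# Air-mass-dependent clear-sky spectral shape, scaled to measured broadband
# irradiance. The shape source plays the role a full atmospheric
# radiative-transfer code (e.g. SMARTS) plays in practice; absolute level
# always comes from the measured global radiation.

#' Wavelength grid
#'
#' Uniform wavelength grid in nanometres spanning exactly 400-1200 nm, the
#' integration limits of the short-circuit-current integral.
#'
#' @param step Grid step in nm; must divide 800 (default 5).
#' @return Numeric vector of wavelengths.
#' @examples
#' head(wavelength_grid())
#' @export
wavelength_grid <- function(step = 5) {
  if (!is.numeric(step) || step <= 0 || (800 %% step) != 0) {
    stop_subsolar("`step` must be a positive divisor of 800 nm.",
                  "subsolar_parameter_error")
  }
  seq(400, 1200, by = step)
}

new_spectral_irradiance <- function(wavelength, value) {
  out <- tibble(wavelength = wavelength, value = value)
  class(out) <- c("spectral_irradiance", class(out))
  out
}

#' Broadband integral of a spectrum
#'
#' Trapezoidal integral of a `wavelength`/`value` tibble over its grid
#' (W m^-2 for a spectral irradiance in W m^-2 nm^-1).
#' @param spec A spectrum tibble with `wavelength` and a value column.
#' @param column Value column name.
#' @return A number.
#' @export
broadband <- function(spec, column = "value") {
  trapz(spec$wavelength, spec[[column]])
}

# ---- parametric clear-sky transmittance provider ------------------------

# Smooth extraterrestrial shape: 5772 K Planck spectral radiance in lambda.
# Only the *shape* matters; every emitted spectrum is renormalized.
planck_shape <- function(lambda_nm, t_sun = 5772) {
  lam <- lambda_nm * 1e-9
  h <- .const$h; cc <- .const$c; kb <- 1.380649e-23
  2 * h * cc^2 / lam^5 / (exp(h * cc / (lam * kb * t_sun)) - 1)
}

# Rayleigh optical depth (lambda in um), SPCTRAL2 parameterization.
tau_rayleigh <- function(lambda_nm) {
  lum <- lambda_nm / 1000
  1 / (lum^4 * (115.6406 - 1.335 / lum^2))
}

# Gaussian band helper for the simplified molecular absorption model.
.band <- function(lambda_nm, center, width, depth) {
  depth * exp(-0.5 * ((lambda_nm - center) / width)^2)
}

# Simplified molecular absorption optical properties: ozone Chappuis band
# plus the main water-vapour bands in 400-1200 nm. `w` scales precipitable
# water (cm), `uo` the ozone column (atm-cm).
absorption_transmittance <- function(lambda_nm, am, w = 1.4, uo = 0.34) {
  k_o3 <- .band(lambda_nm, 600, 55, 0.12) / 0.34       # atm-cm^-1, peak Chappuis
  t_o3 <- exp(-k_o3 * uo * am)
  k_w <- .band(lambda_nm, 723, 12, 0.9) + .band(lambda_nm, 820, 14, 1.0) +
    .band(lambda_nm, 940, 22, 8) + .band(lambda_nm, 1130, 25, 20)
  # saturating water-band transmittance (strong bands grow sublinearly in AM)
  wm <- k_w * w * am
  t_w <- exp(-0.2385 * wm / (1 + 20.07 * wm)^0.45)
  t_o3 * t_w
}

#' Clear-sky spectral shape provider
#'
#' Two interchangeable sources for the normalized, air-mass-dependent
#' clear-sky spectral shape:
#' \describe{
#'   \item{`parametric`}{`shape(lambda; AM) \%prop\%
#'     E_ext(lambda) * T_Rayleigh^AM * T_aerosol^AM * T_absorption(lambda, AM)`
#'     with a Planck extraterrestrial shape, SPCTRAL2-style Rayleigh optical
#'     depth, an Angstrom aerosol term `exp(-beta * lambda_um^-alpha * AM)`,
#'     and a simplified ozone/water-band absorption model.}
#'   \item{`table`}{linear interpolation (in AM) between normalized shapes
#'     tabulated at AM nodes, renormalized after interpolation. The default
#'     table is generated once from the parametric model at nodes
#'     1, 1.5, 2, 3, 5, 10; externally computed spectra (e.g. from SMARTS) can
#'     be supplied instead via `table`.}
#' }
#'
#' @param mode `"table"` (default) or `"parametric"`.
#' @param grid Wavelength grid, nm.
#' @param alpha,beta Angstrom aerosol exponent and turbidity (defaults 1.14, 0.1).
#' @param water Precipitable water, cm (default 1.4).
#' @param ozone Ozone column, atm-cm (default 0.34).
#' @param table Optional shape table: list with `am_nodes` and a
#'   `length(grid) x length(am_nodes)` matrix `shapes` of normalized shapes.
#' @return A `spectral_provider` object.
#' @export
spectral_provider <- function(mode = c("table", "parametric"), grid = wavelength_grid(),
                              alpha = 1.14, beta = 0.1, water = 1.4, ozone = 0.34,
                              table = NULL) {
  mode <- match.arg(mode)
  prov <- structure(
    list(mode = "parametric", grid = grid, alpha = alpha, beta = beta,
         water = water, ozone = ozone),
    class = "spectral_provider"
  )
  if (mode == "table") {
    if (is.null(table)) {
      nodes <- c(1, 1.5, 2, 3, 5, 10)
      shapes <- vapply(nodes, function(a) clear_sky_shape(prov, a)$value,
                       numeric(length(grid)))
      table <- list(am_nodes = nodes, shapes = shapes)
    }
    stopifnot(nrow(table$shapes) == length(grid),
              ncol(table$shapes) == length(table$am_nodes))
    prov$mode <- "table"
    prov$table <- table
  }
  prov
}

#' @export
print.spectral_provider <- function(x, ...) {
  cat(sprintf("<spectral_provider> mode=%s, grid %g-%g nm step %g\n",
              x$mode, min(x$grid), max(x$grid), x$grid[2] - x$grid[1]))
  invisible(x)
}

#' Normalized clear-sky spectral shape at a given air mass
#'
#' @param provider A [spectral_provider()].
#' @param am Air mass, >= 1 (a flagged "no direct sun" value is rejected).
#' @return A `spectral_irradiance` tibble whose trapezoidal integral is 1
#'   (units nm^-1).
#' @examples
#' p <- spectral_provider("parametric")
#' s <- clear_sky_shape(p, 1.5)
#' broadband(s)
#' @export
clear_sky_shape <- function(provider, am) {
  stopifnot(inherits(provider, "spectral_provider"))
  assert_scalar_number(am, "am")
  if (is.na(am) || am < 1) {
    stop_subsolar("`am` must be >= 1 (no direct sun below the horizon cutoff).",
                  "subsolar_parameter_error")
  }
  g <- provider$grid
  if (provider$mode == "parametric") {
    lum <- g / 1000
    v <- planck_shape(g) *
      exp(-tau_rayleigh(g) * am) *
      exp(-provider$beta * lum^(-provider$alpha) * am) *
      absorption_transmittance(g, am, provider$water, provider$ozone)
  } else {
    nodes <- provider$table$am_nodes
    if (am > max(nodes)) {
      rlang::warn(sprintf("air mass %.2f above last table node %.2f; clamped.",
                          am, max(nodes)))
      am <- max(nodes)
    }
    i <- findInterval(am, nodes, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(nodes) - 1L)
    wgt <- (am - nodes[i]) / (nodes[i + 1] - nodes[i])
    v <- (1 - wgt) * provider$table$shapes[, i] + wgt * provider$table$shapes[, i + 1]
  }
  v <- pmax(v, 0)
  new_spectral_irradiance(g, v / trapz(g, v))
}

#' Scale a normalized shape to a measured broadband irradiance
#'
#' @param shape Normalized `spectral_irradiance` (integral 1).
#' @param ghi Measured global horizontal irradiance, W m^-2, >= 0.
#' @return `spectral_irradiance` in W m^-2 nm^-1 whose integral equals `ghi`.
#' @export
scale_to_ghi <- function(shape, ghi) {
  assert_scalar_number(ghi, "ghi")
  if (ghi < 0) {
    stop_subsolar("`ghi` must be >= 0.", "subsolar_parameter_error")
  }
  new_spectral_irradiance(shape$wavelength, shape$value * ghi)
}

#' Load a reference spectrum CSV
#'
#' Reads a two-column CSV (`wavelength_nm,value` in W m^-2 nm^-1; e.g. a
#' terrestrial reference spectrum such as ASTM G173), sorts it, and resamples
#' it onto the wavelength grid by linear interpolation.
#'
#' @param path CSV path.
#' @param grid Target grid, nm.
#' @return A `spectral_irradiance`.
#' @export
load_reference_spectrum <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) {
    stop_subsolar("reference spectrum CSV needs two columns (nm, W m^-2 nm^-1).",
                  "subsolar_format_error")
  }
  lam <- as.numeric(df[[1]]); val <- as.numeric(df[[2]])
  o <- order(lam); lam <- lam[o]; val <- val[o]
  if (min(lam) > min(grid) || max(lam) < max(grid)) {
    stop_subsolar(sprintf("spectrum covers %g-%g nm; needs to cover %g-%g nm.",
                          min(lam), max(lam), min(grid), max(grid)),
                  "subsolar_coverage_error")
  }
  new_spectral_irradiance(grid, approx(lam, val, xout = grid)$y)
}
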