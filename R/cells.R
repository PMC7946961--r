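# Photovoltaic model of the implanted module: subdermal fluence ->
# short-circuit current (EQE integral), irradiance-dependent open-circuit
# voltage, and Pout = FF * VOC * ISC * A.

#' Solar cell specification
#'
#' @param name Cell name.
#' @param eqe Tibble/data frame `wavelength`, `eqe` with EQE in \[0, 1\];
#'   resampled onto `grid` by linear interpolation.
#' @param voc_curve Tibble/data frame `irradiance` (W m^-2, strictly
#'   increasing) and `voc` (V, non-decreasing).
#' @param ff Fill factor in (0, 1\] (default 0.8, typical of efficient
#'   monocrystalline silicon).
#' @param area_cm2 Active area in cm^2 (default 3.6, matching the reference
#'   implantable module).
#' @param grid Wavelength grid, nm.
#' @return A `solar_cell_spec` object.
#' @export
solar_cell_spec <- function(name, eqe, voc_curve, ff = 0.8, area_cm2 = 3.6,
                            grid = wavelength_grid()) {
  eqe <- as_tibble(eqe)
  voc_curve <- as_tibble(voc_curve)
  names(eqe)[1:2] <- c("wavelength", "eqe")
  names(voc_curve)[1:2] <- c("irradiance", "voc")
  if (any(eqe$eqe < 0 | eqe$eqe > 1)) {
    stop_subsolar("EQE values must lie in [0, 1].", "subsolar_validation_error")
  }
  if (ff <= 0 || ff > 1) {
    stop_subsolar("`ff` must lie in (0, 1].", "subsolar_parameter_error")
  }
  if (area_cm2 <= 0) {
    stop_subsolar("`area_cm2` must be positive.", "subsolar_parameter_error")
  }
  if (nrow(voc_curve) < 1 || is.unsorted(voc_curve$irradiance, strictly = TRUE)) {
    stop_subsolar("`voc_curve` irradiances must be strictly increasing.",
                  "subsolar_validation_error")
  }
  if (is.unsorted(voc_curve$voc)) {
    stop_subsolar("`voc_curve` voltages must be non-decreasing.",
                  "subsolar_validation_error")
  }
  eqe_grid <- approx(eqe$wavelength, eqe$eqe, xout = grid, rule = 2)$y
  structure(
    list(name = name, grid = grid, eqe = pmin(1, pmax(0, eqe_grid)),
         voc_curve = voc_curve, ff = ff, area_cm2 = area_cm2),
    class = "solar_cell_spec"
  )
}

#' @export
print.solar_cell_spec <- function(x, ...) {
  cat(sprintf("<solar_cell_spec> %s: FF %.2f, area %.2f cm^2, EQE on %g-%g nm, %d VOC nodes\n",
              x$name, x$ff, x$area_cm2, min(x$grid), max(x$grid), nrow(x$voc_curve)))
  invisible(x)
}

#' Bundled solar cells
#'
#' Two packaged cell specifications: a standard monocrystalline silicon cell
#' and a double-junction GaAs-GaInNAs cell with enhanced 650-1200 nm response
#' (better matched to the red-shifted subdermal spectrum). EQE and VOC curves
#' are synthetic approximations of published datasheet/figure shapes, shipped
#' as replaceable CSVs under `inst/extdata/`.
#'
#' @param name `"mono_si"` or `"gaas_gainnas"`.
#' @param grid Wavelength grid, nm.
#' @param ff Fill factor (default 0.8).
#' @param area_cm2 Active area (default 3.6 cm^2).
#' @return A `solar_cell_spec`.
#' @examples
#' bundled_cell("mono_si")
#' @export
bundled_cell <- function(name = c("mono_si", "gaas_gainnas"),
                         grid = wavelength_grid(), ff = 0.8, area_cm2 = 3.6) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "subsolar", mustWork = TRUE)
  eqe <- utils::read.csv(ext(sprintf("eqe_%s_synthetic.csv", name)))
  voc <- utils::read.csv(ext(sprintf("voc_%s_synthetic.csv", name)))
  solar_cell_spec(name, eqe, voc, ff = ff, area_cm2 = area_cm2, grid = grid)
}

#' Subdermal spectral fluence
#'
#' Pointwise product of the surface spectral irradiance and the skin
#' transmission `zeta(lambda)`: the spectral fluence rate available to the
#' implanted cell, with its broadband (trapezoid) integral attached.
#'
#' @param surface A `spectral_irradiance` (W m^-2 nm^-1).
#' @param zeta A `transmission_spectrum` on the same grid.
#' @return A `subdermal_fluence` tibble `wavelength`, `value`, with attribute
#'   `broadband` (W m^-2).
#' @export
subdermal_fluence <- function(surface, zeta) {
  if (length(surface$wavelength) != length(zeta$wavelength) ||
      any(abs(surface$wavelength - zeta$wavelength) > 1e-9)) {
    stop_subsolar("surface spectrum and transmission are on different grids.",
                  "subsolar_alignment_error")
  }
  out <- tibble(wavelength = surface$wavelength,
                value = surface$value * zeta$zeta)
  attr(out, "broadband") <- trapz(out$wavelength, out$value)
  class(out) <- c("subdermal_fluence", "spectral_irradiance", class(out))
  out
}

#' Short-circuit current density from a subdermal fluence
#'
#' `ISC = integral over 400-1200 nm of phi(lambda) * EQE(lambda) * q dlambda`,
#' with photon flux `phi(lambda) = E(lambda) * lambda / (h c)` (photons
#' m^-2 s^-1 nm^-1 for E in W m^-2 nm^-1), converted to A cm^-2.
#'
#' @param fluence A `subdermal_fluence` (or any `wavelength`/`value` spectrum
#'   in W m^-2 nm^-1).
#' @param eqe EQE values on the same grid (vector in \[0, 1\]), or a
#'   [solar_cell_spec()].
#' @return Current density in A cm^-2.
#' @export
short_circuit_current_density <- function(fluence, eqe) {
  if (inherits(eqe, "solar_cell_spec")) eqe <- eqe$eqe
  if (length(eqe) != length(fluence$wavelength)) {
    stop_subsolar("EQE and fluence are on different grids.", "subsolar_alignment_error")
  }
  if (any(eqe < 0 | eqe > 1)) {
    stop_subsolar("EQE values must lie in [0, 1].", "subsolar_validation_error")
  }
  lam_m <- fluence$wavelength * 1e-9
  integrand <- fluence$value * lam_m / (.const$h * .const$c) * eqe * .const$q
  trapz(fluence$wavelength, integrand) * 1e-4  # A m^-2 -> A cm^-2
}

#' Open-circuit voltage at a broadband fluence
#'
#' Interpolates the cell's VOC curve linearly in `log(irradiance)` (the
#' diode-physics scaling). Below the lowest node the same log-linear slope is
#' extrapolated and floored at 0 V; above the highest node the value is
#' clamped. A broadband fluence of exactly 0 gives 0 V.
#'
#' @param spec A [solar_cell_spec()].
#' @param broadband Broadband subdermal fluence, W m^-2, >= 0.
#' @return Volts (vectorized over `broadband`).
#' @export
voc_at <- function(spec, broadband) {
  if (any(broadband < 0)) {
    stop_subsolar("`broadband` must be >= 0.", "subsolar_parameter_error")
  }
  cv <- spec$voc_curve
  out <- numeric(length(broadband))
  pos <- broadband > 0
  if (any(pos)) {
    lx <- log(cv$irradiance)
    if (nrow(cv) == 1) {
      out[pos] <- cv$voc[1]
    } else {
      slope_lo <- (cv$voc[2] - cv$voc[1]) / (lx[2] - lx[1])
      q <- log(broadband[pos])
      v <- approx(lx, cv$voc, xout = q, rule = 2)$y
      below <- q < lx[1]
      v[below] <- cv$voc[1] + slope_lo * (q[below] - lx[1])
      out[pos] <- pmax(0, v)
    }
  }
  out
}

#' Output power of the module
#'
#' `Pout = FF * VOC * ISC * A` with ISC in A cm^-2 and A in cm^2.
#'
#' @param spec A [solar_cell_spec()].
#' @param isc Short-circuit current density, A cm^-2, >= 0.
#' @param voc Open-circuit voltage, V, >= 0.
#' @return Power in watts (vectorized).
#' @export
output_power <- function(spec, isc, voc) {
  if (any(isc < 0) || any(voc < 0)) {
    stop_subsolar("`isc` and `voc` must be >= 0.", "subsolar_parameter_error")
  }
  spec$ff * voc * isc * spec$area_cm2
}
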