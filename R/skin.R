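# Layered skin model and wavelength-resolved transmission to the implant
# plane, by Monte Carlo photon transport or from a measured table.

#' Layer absorption from chromophore volume fractions
#'
#' Volume-fraction-weighted absorption coefficient of a skin layer:
#' `mu_a(lambda) = sum_i VF_i * mu_a,i(lambda)` over blood, water, fat,
#' melanosome and the baseline remainder ("other").
#'
#' @param vf Named numeric vector of volume fractions, names among
#'   `blood`, `water`, `fat`, `melanosome`, `other`; each in \[0, 1\].
#' @param lambda Wavelength(s), nm.
#' @param mua_funs Optional named list of override functions `f(lambda)`
#'   (e.g. from [chromophore_from_csv()]); defaults to the bundled spectra.
#' @return mu_a in cm^-1.
#' @examples
#' layer_mua(c(blood = 0.02, water = 0.75, fat = 0.2,
#'             melanosome = 0.01, other = 0.02), 500)
#' @export
layer_mua <- function(vf, lambda, mua_funs = NULL) {
  allowed <- c("blood", "water", "fat", "melanosome", "other")
  if (is.null(names(vf)) || !all(names(vf) %in% allowed)) {
    stop_subsolar("`vf` must be named with chromophores among blood/water/fat/melanosome/other.",
                  "subsolar_parameter_error")
  }
  if (any(vf < 0 | vf > 1)) {
    stop_subsolar("volume fractions must lie in [0, 1].", "subsolar_parameter_error")
  }
  if (sum(vf) > 1 + 1e-9) {
    rlang::warn(sprintf("volume fractions sum to %.4f (> 1); used as given.", sum(vf)))
  }
  out <- numeric(length(lambda))
  for (nm in names(vf)) {
    f <- if (!is.null(mua_funs[[nm]])) mua_funs[[nm]] else function(l) chromophore_mua(nm, l)
    out <- out + vf[[nm]] * f(lambda)
  }
  out
}

#' Reduced scattering coefficient power law
#'
#' Empirical wavelength scaling `mu_s'(lambda) = a * (lambda / 500 nm)^(-b)`.
#'
#' @param a Scaling at 500 nm, cm^-1 (>= 0).
#' @param b Scattering power (dimensionless).
#' @param lambda Wavelength(s), nm, > 0.
#' @return mu_s' in cm^-1.
#' @examples
#' layer_musp(60, 1.4, 1000)
#' @export
layer_musp <- function(a, b, lambda) {
  if (!is.numeric(a) || any(a < 0)) {
    stop_subsolar("`a` must be >= 0.", "subsolar_parameter_error")
  }
  if (any(lambda <= 0)) {
    stop_subsolar("`lambda` must be positive.", "subsolar_parameter_error")
  }
  a * (lambda / 500)^(-b)
}

#' Layered skin model
#'
#' Ordered optical layers, surface down, plus the implant depth. The bundled
#' default (see [skin_type_vi()]) is a heavily pigmented (phototype VI)
#' three-layer stack with total thickness 2.5 mm.
#'
#' @param layers A data frame / tibble with columns `name`, `thickness_cm`,
#'   `a`, `b` (reduced-scattering power law), `g` (anisotropy), `n`
#'   (refractive index), and a list-column `vf` of named volume-fraction
#'   vectors (or `NULL` with a `mua_fun` list-column of functions f(lambda)).
#' @param scd Implant depth below the surface, cm (default 0.25 = 2.5 mm).
#' @param n_ambient Refractive index above the skin (default 1).
#' @return A `skin_model` object.
#' @export
skin_model <- function(layers, scd = 0.25, n_ambient = 1.0) {
  layers <- as_tibble(layers)
  need <- c("name", "thickness_cm", "a", "b", "g", "n")
  if (!all(need %in% names(layers))) {
    stop_subsolar(sprintf("`layers` needs columns %s.", paste(need, collapse = ", ")),
                  "subsolar_parameter_error")
  }
  if (any(layers$thickness_cm <= 0)) {
    stop_subsolar("layer thicknesses must be positive.", "subsolar_parameter_error")
  }
  if (any(layers$g < 0 | layers$g >= 1) || any(layers$n < 1)) {
    stop_subsolar("need 0 <= g < 1 and n >= 1 for every layer.", "subsolar_parameter_error")
  }
  total <- sum(layers$thickness_cm)
  if (scd <= 0 || scd > total + 1e-12) {
    stop_subsolar(sprintf("implant depth scd = %g cm must lie in (0, %g] (total stack).",
                          scd, total), "subsolar_parameter_error")
  }
  structure(list(layers = layers, scd = scd, n_ambient = n_ambient),
            class = "skin_model")
}

#' @export
print.skin_model <- function(x, ...) {
  cat(sprintf("<skin_model> %d layers, total %.3f cm, implant at %.3f cm\n",
              nrow(x$layers), sum(x$layers$thickness_cm), x$scd))
  print(dplyr::select(x$layers, -dplyr::any_of(c("vf", "mua_fun"))))
  invisible(x)
}

#' Bundled phototype VI skin model
#'
#' Three-layer stack (epidermis 0.1 mm, dermis 1.4 mm, subcutis 1.0 mm;
#' total 2.5 mm — only the total is constrained by the underlying
#' measurements, the split is a documented default). Volume fractions follow
#' the published phototype VI values; anisotropy g = 0.9 throughout;
#' n = 1.34 (epidermis) and 1.41 (dermis, subcutis). Note the subcutis
#' volume fractions sum to 1.0945 as printed in the source table; they are
#' used as given (a warning is raised when the absorption is evaluated).
#'
#' @param scd Implant depth, cm (default 0.25).
#' @return A `skin_model`.
#' @examples
#' skin_type_vi()
#' @export
skin_type_vi <- function(scd = 0.25) {
  layers <- tibble(
    name = c("epidermis", "dermis", "subcutis"),
    thickness_cm = c(0.01, 0.14, 0.10),
    a = c(80, 60, 40),
    b = c(1.15, 1.4, 1.0),
    g = 0.9,
    n = c(1.34, 1.41, 1.41),
    vf = list(
      c(blood = 0, water = 0.65, fat = 0.1, melanosome = 0.0165, other = 0.2335),
      c(blood = 0.02, water = 0.75, fat = 0.2, melanosome = 0.01, other = 0.02),
      c(blood = 0.08, water = 0.7, fat = 0.2, melanosome = 0.0095, other = 0.105)
    )
  )
  skin_model(layers, scd = scd)
}

# Resolve (mua, mus, g, n, thickness) for every layer at one wavelength.
resolve_optics <- function(model, lambda) {
  ly <- model$layers
  mua <- vapply(seq_len(nrow(ly)), function(i) {
    if (!is.null(ly$vf) && !is.null(ly$vf[[i]])) {
      suppressWarnings(layer_mua(ly$vf[[i]], lambda))
    } else if (!is.null(ly$mua_fun) && !is.null(ly$mua_fun[[i]])) {
      ly$mua_fun[[i]](lambda)
    } else {
      stop_subsolar("layer has neither `vf` nor `mua_fun`.", "subsolar_parameter_error")
    }
  }, numeric(1))
  musp <- layer_musp(ly$a, ly$b, lambda)
  list(thickness = ly$thickness_cm, mua = mua, mus = musp / (1 - ly$g),
       g = ly$g, n = ly$n)
}

#' Monte Carlo transmission to the implant plane at one wavelength
#'
#' Weighted-photon transport through the laterally infinite layered slab:
#' collimated normal launch with specular Fresnel loss at the air-epidermis
#' interface, exponential free paths with `mu_t = mu_a + mu_s`, fractional
#' absorption deposition, Henyey-Greenstein scattering, Fresnel
#' reflection/refraction at internal index mismatches, and Russian roulette
#' below the weight threshold. The implant plane at depth `scd` is a perfect
#' absorber by default; `zeta` is the weight fraction absorbed there.
#' `plane = "transparent"` instead scores the weight arriving at the plane
#' for the first time and lets photons continue (free-passage scoring).
#'
#' @param model A [skin_model()].
#' @param lambda Wavelength, nm.
#' @param n_photons Photon count (>= 1000; default 1e5).
#' @param seed Integer seed of the wavelength's RNG substream.
#' @param plane `"absorbing"` (default) or `"transparent"`.
#' @param roulette_threshold,roulette_survive Roulette weight threshold and
#'   survival probability (defaults 1e-4 and 0.1).
#' @return A list: `zeta`, `stderr`, and `ledger` (named weights: `specular`,
#'   `reflected`, `absorbed_tissue`, `absorbed_plane`, `transmitted`,
#'   `roulette_net`; all per launched unit weight). In absorbing mode the
#'   ledger sums to 1 up to the roulette noise term, and including
#'   `roulette_net` it sums to 1 to floating-point accuracy.
#' @examples
#' m <- skin_type_vi()
#' mc_transmission(m, 700, n_photons = 5000, seed = 1)$zeta
#' @export
mc_transmission <- function(model, lambda, n_photons = 1e5, seed = 1L,
                            plane = c("absorbing", "transparent"),
                            roulette_threshold = 1e-4, roulette_survive = 0.1) {
  stopifnot(inherits(model, "skin_model"))
  plane <- match.arg(plane)
  if (n_photons < 1000) {
    stop_subsolar("`n_photons` must be >= 1000.", "subsolar_parameter_error")
  }
  op <- resolve_optics(model, lambda)
  res <- mc_slab_transmission(
    op$thickness, op$mua, op$mus, op$g, op$n,
    model$n_ambient, model$scd, as.integer(n_photons),
    as.numeric(seed), plane == "absorbing",
    roulette_threshold, roulette_survive
  )
  res
}

#' Transmission spectrum over a wavelength grid
#'
#' Runs [mc_transmission()] at every grid wavelength with an independent
#' seed-derived RNG substream per wavelength (same `seed` gives a
#' bit-identical spectrum; wavelengths are mutually independent).
#'
#' @param model A [skin_model()].
#' @param grid Wavelength grid, nm.
#' @param n_photons Photons per wavelength.
#' @param seed Integer master seed.
#' @inheritParams mc_transmission
#' @return A `transmission_spectrum` tibble: `wavelength`, `zeta`, `stderr`.
#' @export
transmission_spectrum <- function(model, grid = wavelength_grid(),
                                  n_photons = 1e5, seed = 1L,
                                  plane = c("absorbing", "transparent")) {
  plane <- match.arg(plane)
  rows <- purrr::map(seq_along(grid), function(i) {
    r <- mc_transmission(model, grid[i], n_photons = n_photons,
                         seed = seed * 100003 + i, plane = plane)
    tibble(wavelength = grid[i], zeta = r$zeta, stderr = r$stderr)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("transmission_spectrum", class(out))
  out
}

#' Load a measured transmission spectrum CSV
#'
#' Two-column CSV `wavelength_nm,zeta` with zeta in \[0, 1\] (e.g. the
#' measured transmission of light phototype I/II skin), resampled onto the
#' grid by linear interpolation; `stderr` is 0 for measured tables.
#'
#' @param path CSV path.
#' @param grid Target grid, nm.
#' @return A `transmission_spectrum`.
#' @export
load_transmission_csv <- function(path, grid = wavelength_grid()) {
  df <- utils::read.csv(path)
  lam <- as.numeric(df[[1]]); z <- as.numeric(df[[2]])
  o <- order(lam); lam <- lam[o]; z <- z[o]
  if (any(z < 0 | z > 1, na.rm = TRUE)) {
    stop_subsolar("transmission values must lie in [0, 1].", "subsolar_validation_error")
  }
  if (min(lam) > min(grid) || max(lam) < max(grid)) {
    stop_subsolar(sprintf("transmission covers %g-%g nm; needs %g-%g nm.",
                          min(lam), max(lam), min(grid), max(grid)),
                  "subsolar_coverage_error")
  }
  out <- tibble(wavelength = grid, zeta = approx(lam, z, xout = grid)$y, stderr = 0)
  class(out) <- c("transmission_spectrum", class(out))
  out
}

#' Write a transmission spectrum CSV
#' @param spectrum A `transmission_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transmission_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(wavelength_nm = spectrum$wavelength, zeta = spectrum$zeta),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Bundled synthetic phototype I/II transmission spectrum
#'
#' Loads the packaged approximation of the measured light-skin (phototype
#' I/II) transmission through 2.5 mm of tissue. The file is synthetic: a
#' smooth curve matching the qualitative behaviour of published measurements
#' (a few percent in the blue, rising to tens of percent in the near
#' infrared, with a water dip near 970 nm), not digitized data.
#'
#' @param grid Wavelength grid, nm.
#' @return A `transmission_spectrum`.
#' @export
skin_type_i_ii <- function(grid = wavelength_grid()) {
  load_transmission_csv(
    system.file("extdata", "skin_type_I_II_transmission_synthetic.csv",
                package = "subsolar", mustWork = TRUE),
    grid
  )
}
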