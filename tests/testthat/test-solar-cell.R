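test_that("subdermal fluence is the pointwise product with its broadband attached", {
  g <- wavelength_grid(50)
  p <- spectral_provider("table", grid = g)
  surf <- scale_to_ghi(clear_sky_shape(p, 1.5), 600)

  pass <- unit_skin(g)
  expect_equal(subdermal_fluence(surf, pass)$value, surf$value)

  block <- pass; block$zeta <- 0
  expect_true(all(subdermal_fluence(surf, block)$value == 0))

  half <- pass; half$zeta <- 0.5
  flat <- structure(tibble::tibble(wavelength = g, value = 1),
                    class = c("spectral_irradiance", class(tibble::tibble())))
  fl <- subdermal_fluence(flat, half)
  expect_equal(attr(fl, "broadband"), 400)  # 0.5 * 800 nm span

  other <- unit_skin(wavelength_grid(100))
  expect_error(subdermal_fluence(surf, other), class = "subsolar_alignment_error")
})

test_that("short-circuit current integrates the EQE-weighted photon flux", {
  g <- wavelength_grid(5)
  zero <- tibble::tibble(wavelength = g, value = 0)
  expect_equal(short_circuit_current_density(zero, rep(1, length(g))), 0)

  # 1 W m^-2 concentrated at 1000 nm with unit EQE: q * lambda / (h c)
  dl <- 5
  mono <- tibble::tibble(wavelength = g, value = ifelse(g == 1000, 1 / dl, 0))
  want <- 1 * 1000e-9 / (6.62607015e-34 * 2.99792458e8) * 1.602176634e-19 * 1e-4
  expect_equal(short_circuit_current_density(mono, rep(1, length(g))), want,
               tolerance = 1e-9)
  expect_equal(want, 8.06e-5, tolerance = 2e-3)

  # linearity in the fluence
  s <- tibble::tibble(wavelength = g, value = 0.3 + g / 2000)
  s2 <- s; s2$value <- 2 * s$value
  eqe <- pmin(1, g / 1200)
  expect_equal(short_circuit_current_density(s2, eqe),
               2 * short_circuit_current_density(s, eqe))

  expect_error(short_circuit_current_density(s, rep(1.2, length(g))),
               class = "subsolar_validation_error")
})

test_that("ISC is stable under grid refinement for smooth spectra", {
  isc_on <- function(step) {
    g <- wavelength_grid(step)
    surf <- scale_to_ghi(clear_sky_shape(spectral_provider("parametric", grid = g), 1.5), 1000)
    short_circuit_current_density(surf, bundled_cell("mono_si", grid = g)$eqe)
  }
  expect_equal(isc_on(5), isc_on(1), tolerance = 0.005)
})

test_that("VOC interpolates log-linearly with floor and clamp", {
  cv <- data.frame(irradiance = c(10, 100), voc = c(0.40, 0.46))
  spec <- solar_cell_spec("toy", data.frame(wavelength = c(400, 1200), eqe = c(1, 1)), cv)
  expect_equal(voc_at(spec, 10), 0.40)
  expect_equal(voc_at(spec, 100), 0.46)
  expect_equal(voc_at(spec, sqrt(10 * 100)), 0.43, tolerance = 1e-12)
  expect_equal(voc_at(spec, 0), 0)
  expect_equal(voc_at(spec, 1000), 0.46)      # clamped above
  expect_gt(voc_at(spec, 5), 0.3)             # extrapolated below on the same slope
  expect_equal(voc_at(spec, 1e-12), 0)        # floored at 0 V
  expect_error(voc_at(spec, -1), class = "subsolar_parameter_error")
})

test_that("output power is the FF * VOC * ISC * A product with its scalings", {
  spec <- bundled_cell("mono_si")
  expect_equal(output_power(spec, 1e-3, 0.5), 0.8 * 0.5 * 1e-3 * 3.6)
  expect_equal(0.8 * 0.5 * 1e-3 * 3.6, 1.44e-3)
  expect_equal(output_power(spec, 0, 0.7), 0)
  big <- bundled_cell("mono_si", area_cm2 = 7.2)
  expect_equal(output_power(big, 1e-3, 0.5), 2 * output_power(spec, 1e-3, 0.5))
  expect_error(output_power(spec, -1, 0.5), class = "subsolar_parameter_error")
})

test_that("power ratio of two cells under the same fluence is area-independent", {
  g <- wavelength_grid(25)
  p <- spectral_provider("parametric", grid = g)
  skin <- skin_type_i_ii(g)
  fl <- subdermal_fluence(scale_to_ghi(clear_sky_shape(p, 1.5), 800), skin)
  bb <- attr(fl, "broadband")
  pout <- function(nm, area) {
    cell <- bundled_cell(nm, grid = g, area_cm2 = area)
    output_power(cell, short_circuit_current_density(fl, cell$eqe), voc_at(cell, bb))
  }
  r1 <- pout("gaas_gainnas", 3.6) / pout("mono_si", 3.6)
  r2 <- pout("gaas_gainnas", 1.0) / pout("mono_si", 1.0)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("cell specification validates its curves", {
  eqe <- data.frame(wavelength = c(400, 1200), eqe = c(0.5, 0.5))
  expect_error(solar_cell_spec("x", data.frame(wavelength = 500, eqe = 1.2),
                               data.frame(irradiance = 1, voc = 0.5)),
               class = "subsolar_validation_error")
  expect_error(solar_cell_spec("x", eqe, data.frame(irradiance = c(10, 10), voc = c(0.4, 0.5))),
               class = "subsolar_validation_error")
  expect_error(solar_cell_spec("x", eqe, data.frame(irradiance = c(10, 20), voc = c(0.5, 0.4))),
               class = "subsolar_validation_error")
  expect_error(solar_cell_spec("x", eqe, data.frame(irradiance = 1, voc = 0.5), ff = 0),
               class = "subsolar_parameter_error")
})
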