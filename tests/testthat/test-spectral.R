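test_that("clear-sky shapes are normalized, red-shift with air mass, and vary continuously", {
  for (p in list(spectral_provider("parametric"), spectral_provider("table"))) {
    for (am in c(1, 1.5, 2.7, 5, 10)) {
      s <- clear_sky_shape(p, am)
      expect_equal(broadband(s), 1, tolerance = 1e-9)
      expect_true(all(s$value >= 0))
    }
    s1 <- clear_sky_shape(p, 1); s5 <- clear_sky_shape(p, 5)
    ratio <- function(s) s$value[s$wavelength == 450] / s$value[s$wavelength == 800]
    expect_lt(ratio(s5), ratio(s1))

    # continuity in AM: neighbouring shapes differ by a small sup-norm bound
    for (am in c(1.2, 1.9, 3.4, 6)) {
      a <- clear_sky_shape(p, am)$value
      b <- clear_sky_shape(p, am + 0.01)$value
      expect_lt(max(abs(a - b)), 0.01 * max(a))
    }
    expect_error(clear_sky_shape(p, 0.8), class = "subsolar_parameter_error")
  }
})

test_that("table mode reproduces its nodes and clamps beyond the last one", {
  p <- spectral_provider("table")
  par <- spectral_provider("parametric")
  for (node in p$table$am_nodes) {
    expect_equal(clear_sky_shape(p, node)$value, clear_sky_shape(par, node)$value,
                 tolerance = 1e-12)
  }
  expect_warning(s <- clear_sky_shape(p, 25), "clamped")
  expect_equal(s$value, clear_sky_shape(par, 10)$value, tolerance = 1e-12)
})

test_that("scaling to measured irradiance conserves broadband energy and is linear", {
  p <- spectral_provider("table")
  s <- clear_sky_shape(p, 1.8)
  expect_true(all(scale_to_ghi(s, 0)$value == 0))
  expect_equal(broadband(scale_to_ghi(s, 500)), 500, tolerance = 1e-6)
  expect_equal(scale_to_ghi(s, 2 * 123.4)$value, 2 * scale_to_ghi(s, 123.4)$value)
  expect_error(scale_to_ghi(s, -1), class = "subsolar_parameter_error")
})

test_that("energy closure holds for every record of a synthetic day", {
  m <- station_meta("ML", 45, 8)
  s <- synthesize_series(m, 2015, step = 3, seed = 5)
  day <- s[format(s$timestamp, "%m-%d") == "06-15" & s$ghi > 0, ]
  z <- solar_zenith(m, day$timestamp)$zenith
  amr <- air_mass(pmin(z, 84.9))
  p <- spectral_provider("table")
  for (i in seq(1, nrow(day), by = 17)) {
    sc <- scale_to_ghi(clear_sky_shape(p, amr$air_mass[i]), day$ghi[i])
    expect_equal(broadband(sc), day$ghi[i], tolerance = 1e-6)
  }
})

test_that("reference-spectrum loader resamples and conserves the integral", {
  # flat 1 W m^-2 nm^-1 -> 800 W m^-2 over the 400-1200 nm span
  f <- write_tmp_csv(c("wavelength_nm,value",
                       paste(seq(350, 1250, by = 10), 1, sep = ",")))
  s <- load_reference_spectrum(f)
  expect_equal(broadband(s), 800, tolerance = 1e-9)

  # shuffled rows give the same result as sorted input
  lam <- seq(380, 1220, by = 7)
  val <- 1 + 0.5 * sin(lam / 90)
  idx <- sample(length(lam))
  f_sorted <- write_tmp_csv(c("wavelength_nm,value", paste(lam, val, sep = ",")))
  f_shuf <- write_tmp_csv(c("wavelength_nm,value", paste(lam[idx], val[idx], sep = ",")))
  expect_equal(load_reference_spectrum(f_shuf)$value,
               load_reference_spectrum(f_sorted)$value)

  # sub-grid-resolution input: resampling conserves the integral within 1%
  lam2 <- seq(399, 1202.4, by = 1.3)
  val2 <- 1 + 0.4 * cos(lam2 / 120)
  f2 <- write_tmp_csv(c("wavelength_nm,value", paste(lam2, val2, sep = ",")))
  before <- pracma::trapz(lam2[lam2 >= 400 & lam2 <= 1200], val2[lam2 >= 400 & lam2 <= 1200])
  expect_equal(broadband(load_reference_spectrum(f2)), before, tolerance = 0.01)

  # insufficient coverage errors
  f3 <- write_tmp_csv(c("wavelength_nm,value", paste(seq(500, 1100, 10), 1, sep = ",")))
  expect_error(load_reference_spectrum(f3), class = "subsolar_coverage_error")
})

test_that("wavelength grid enforces its bounds and step", {
  g <- wavelength_grid()
  expect_equal(range(g), c(400, 1200))
  expect_equal(wavelength_grid(100), seq(400, 1200, 100))
  expect_error(wavelength_grid(7), class = "subsolar_parameter_error")
})
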