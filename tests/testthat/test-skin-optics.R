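test_that("layer absorption is the volume-fraction-weighted chromophore sum", {
  # constant unit spectra with fractions summing to 1 give the constant back
  const1 <- function(l) rep(1, length(l))
  funs <- list(blood = const1, water = const1, fat = const1,
               melanosome = const1, other = const1)
  vf <- c(blood = 0.2, water = 0.3, fat = 0.1, melanosome = 0.15, other = 0.25)
  expect_equal(layer_mua(vf, 700, funs), 1)

  # published phototype VI epidermis weights on a water-only unit spectrum
  zero <- function(l) rep(0, length(l))
  funs2 <- list(blood = zero, water = const1, fat = zero,
                melanosome = zero, other = zero)
  vf_epi <- c(blood = 0, water = 0.65, fat = 0.1, melanosome = 0.0165, other = 0.2335)
  expect_equal(layer_mua(vf_epi, 550, funs2), 0.65)

  # bundled dermis absorption at 500 nm equals an independent five-term sum
  vf_derm <- c(blood = 0.02, water = 0.75, fat = 0.2, melanosome = 0.01, other = 0.02)
  hand <- sum(vapply(names(vf_derm),
                     function(nm) vf_derm[[nm]] * chromophore_mua(nm, 500),
                     numeric(1)))
  expect_equal(layer_mua(vf_derm, 500), hand)

  expect_error(layer_mua(c(blood = 1.2), 500), class = "subsolar_parameter_error")
  expect_error(layer_mua(c(unknown = 0.1), 500), class = "subsolar_parameter_error")
  expect_warning(layer_mua(c(water = 0.7, fat = 0.5), 500), "sum to")
  expect_error(chromophore_mua("water", 1300), class = "subsolar_coverage_error")
})

test_that("reduced scattering follows the 500-nm-referenced power law", {
  expect_equal(layer_musp(80, 1.15, 500), 80)
  expect_equal(layer_musp(60, 1.4, 1000), 60 * 2^(-1.4), tolerance = 1e-12)
  expect_equal(layer_musp(35, 0, c(400, 800, 1200)), rep(35, 3))
  expect_error(layer_musp(-5, 1, 600), class = "subsolar_parameter_error")
  expect_error(layer_musp(60, 1, 0), class = "subsolar_parameter_error")
})

test_that("Monte Carlo transmission matches Beer-Lambert in the absorbing-slab limit", {
  m <- absorbing_slab(mua = 2, scd = 0.25)
  r <- mc_transmission(m, 700, n_photons = 1e5, seed = 3)
  expect_lt(abs(r$zeta - exp(-2 * 0.25)), 3 * r$stderr)

  # nothing removes photons in a vacuum slab with matched indices
  m0 <- absorbing_slab(mua = 0, scd = 0.25)
  r0 <- mc_transmission(m0, 700, n_photons = 2000, seed = 1)
  expect_identical(r0$zeta, 1)
  expect_identical(r0$stderr, 0)
})

test_that("every MC run conserves weight", {
  configs <- list(
    list(m = skin_type_vi(), lam = 450),
    list(m = skin_type_vi(), lam = 700),
    list(m = skin_type_vi(), lam = 980),
    list(m = turbid_slab(mua = 1), lam = 700),
    list(m = absorbing_slab(mua = 3), lam = 700)
  )
  for (cf in configs) {
    r <- suppressWarnings(mc_transmission(cf$m, cf$lam, n_photons = 1e5, seed = 11))
    # full ledger (incl. the roulette imbalance term) sums exactly
    expect_equal(sum(r$ledger), 1, tolerance = 1e-9)
    # the four physical categories alone agree to the roulette noise floor
    four <- sum(r$ledger[c("specular", "reflected", "absorbed_tissue",
                           "absorbed_plane", "transmitted")])
    expect_equal(four, 1, tolerance = 1e-6)
  }
})

test_that("transmission decreases with implant depth and with absorption", {
  depths <- c(0.08, 0.15, 0.25)
  z_depth <- vapply(depths, function(d) {
    suppressWarnings(mc_transmission(skin_type_vi(scd = d), 800,
                                     n_photons = 2e4, seed = 5)$zeta)
  }, numeric(1))
  expect_true(all(diff(z_depth) < 0))

  mus_abs <- c(0.5, 2, 8)
  z_abs <- vapply(mus_abs, function(a) {
    mc_transmission(turbid_slab(mua = a), 700, n_photons = 2e4, seed = 5)$zeta
  }, numeric(1))
  expect_true(all(diff(z_abs) < 0))
})

test_that("MC standard error scales like 1/sqrt(n) over a decade", {
  m <- turbid_slab(mua = 1)
  se1 <- mc_transmission(m, 700, n_photons = 2e3, seed = 2)$stderr
  se10 <- mc_transmission(m, 700, n_photons = 2e4, seed = 2)$stderr
  expect_equal(se1 / se10, sqrt(10), tolerance = 0.35)
})

test_that("transmission spectra are deterministic per seed with per-wavelength substreams", {
  m <- skin_type_vi()
  g <- c(500, 700, 900)
  a <- suppressWarnings(transmission_spectrum(m, g, n_photons = 3000, seed = 9))
  b <- suppressWarnings(transmission_spectrum(m, g, n_photons = 3000, seed = 9))
  expect_identical(a$zeta, b$zeta)
  expect_equal(nrow(a), 3)
  expect_true(all(a$stderr > 0))

  # melanin dominates the blue: more light reaches the implant at 700 nm
  expect_gt(a$zeta[a$wavelength == 700], a$zeta[a$wavelength == 500])
})

test_that("measured transmission tables load, validate, and round-trip", {
  g <- wavelength_grid(100)
  f <- write_tmp_csv(c("wavelength_nm,zeta", paste(seq(400, 1200, 50), 0.5, sep = ",")))
  ts <- load_transmission_csv(f, g)
  expect_equal(ts$zeta, rep(0.5, length(g)))
  expect_true(all(ts$stderr == 0))

  f_bad <- write_tmp_csv(c("wavelength_nm,zeta", "400,0.5", "1200,1.4"))
  expect_error(load_transmission_csv(f_bad, g), class = "subsolar_validation_error")
  f_cov <- write_tmp_csv(c("wavelength_nm,zeta", "500,0.5", "1100,0.5"))
  expect_error(load_transmission_csv(f_cov, g), class = "subsolar_coverage_error")

  out <- tempfile(fileext = ".csv")
  write_transmission_csv(ts, out)
  expect_equal(load_transmission_csv(out, g)$zeta, ts$zeta)

  # bundled light-skin table rises from blue to near-infrared
  sk <- skin_type_i_ii(g)
  expect_gt(sk$zeta[sk$wavelength == 800], sk$zeta[sk$wavelength == 500])
})

test_that("skin model validates geometry", {
  expect_error(skin_type_vi(scd = 0.3), class = "subsolar_parameter_error")
  expect_error(skin_type_vi(scd = 0), class = "subsolar_parameter_error")
  expect_error(mc_transmission(skin_type_vi(), 700, n_photons = 10),
               class = "subsolar_parameter_error")
})
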