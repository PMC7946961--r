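# Shared fixtures and independent oracles.

# Independent scalar transcription of the NOAA low-precision solar position
# (used only as an oracle against the vectorized implementation).
noaa_zenith_oracle <- function(lat, lon, t) {
  t <- as.POSIXct(t, tz = "UTC")
  yr <- as.integer(format(t, "%Y"))
  leap <- (yr %% 4 == 0 && yr %% 100 != 0) || yr %% 400 == 0
  nd <- if (leap) 366 else 365
  doy <- as.integer(format(t, "%j"))
  hh <- as.integer(format(t, "%H")); mm <- as.integer(format(t, "%M"))
  ss <- as.numeric(format(t, "%S"))
  g <- 2 * pi / nd * (doy - 1 + (hh - 12) / 24)
  eq <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  dec <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hh * 60 + mm + ss / 60 + eq + 4 * lon
  ha <- tst / 4 - 180
  cz <- sin(lat * pi / 180) * sin(dec) +
    cos(lat * pi / 180) * cos(dec) * cos(ha * pi / 180)
  acos(max(-1, min(1, cz))) * 180 / pi
}

# A homogeneous purely absorbing, index-matched slab: transmission to the
# plane has the Beer-Lambert closed form exp(-mua * scd).
absorbing_slab <- function(mua, thickness = 0.5, scd = 0.25, n = 1.0) {
  skin_model(
    tibble::tibble(name = "slab", thickness_cm = thickness, a = 0, b = 1,
                   g = 0.9, n = n, vf = list(NULL),
                   mua_fun = list(local({m <- mua; function(l) m}))),
    scd = scd, n_ambient = 1.0
  )
}

# scattering slab with tunable absorption, matched indices
turbid_slab <- function(mua, a = 20, thickness = 0.5, scd = 0.25) {
  skin_model(
    tibble::tibble(name = "slab", thickness_cm = thickness, a = a, b = 1,
                   g = 0.9, n = 1.0, vf = list(NULL),
                   mua_fun = list(local({m <- mua; function(l) m}))),
    scd = scd, n_ambient = 1.0
  )
}

# unit-transmission "skin" and idealized cell on a grid, for pipeline oracles
unit_skin <- function(grid) {
  out <- tibble::tibble(wavelength = grid, zeta = 1, stderr = 0)
  class(out) <- c("transmission_spectrum", class(out))
  out
}

ideal_cell <- function(grid, ff = 1, area = 3.6,
                       voc = data.frame(irradiance = c(1, 1000), voc = c(0.5, 0.5))) {
  solar_cell_spec("ideal", data.frame(wavelength = grid, eqe = 1), voc,
                  ff = ff, area_cm2 = area, grid = grid)
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
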