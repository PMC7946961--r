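# Bundled chromophore absorption spectra, 400-1200 nm, in cm^-1.
#
# These are tabulated/parametric approximations assembled from the standard
# tissue-optics compilations (Hale & Querry water, Prahl haemoglobin molar
# extinctions, van Veen lipid, Jacques melanosome and baseline). They are
# smooth approximations suitable for layer-averaged absorption, not
# metrology-grade data, and every one can be overridden with a user CSV
# (`wavelength_nm,mua_cm1`) via [chromophore_from_csv()].

# molar extinction anchors, cm^-1 / (mol L^-1); whole blood assumed
# 150 g haemoglobin per litre, 64500 g/mol, 75% oxygen saturation.
.hb_tab <- data.frame(
  lambda = c(400, 420, 450, 500, 540, 560, 580, 600, 650, 700, 750, 800,
             850, 900, 950, 1000, 1100, 1200),
  hbo2 = c(266232, 480360, 62816, 20932, 53236, 32610, 50104, 3200, 368,
           290, 586, 816, 1058, 1198, 1204, 1086, 1000, 900),
  hb = c(223296, 103292, 103292, 20862, 53236, 53788, 37020, 14677, 3750,
         1794, 1405, 762, 692, 726, 579, 418, 300, 250)
)

.water_tab <- data.frame(
  lambda = c(400, 450, 500, 550, 600, 650, 700, 750, 800, 850, 900, 950,
             1000, 1050, 1100, 1150, 1200),
  mua = c(0.00058, 0.00029, 0.00025, 0.00045, 0.0023, 0.0032, 0.006, 0.0261,
          0.0196, 0.0433, 0.0679, 0.388, 0.363, 0.119, 0.178, 0.83, 1.04)
)

.fat_tab <- data.frame(
  lambda = c(400, 500, 600, 700, 800, 900, 930, 960, 1000, 1100, 1150, 1200),
  mua = c(0.02, 0.01, 0.007, 0.007, 0.008, 0.03, 0.1, 0.05, 0.02, 0.04, 0.1, 0.6)
)

loglin_interp <- function(tab, lambda) {
  exp(approx(tab$lambda, log(pmax(tab[[2]], 1e-12)), xout = lambda, rule = 2)$y)
}

#' Bundled chromophore absorption spectra
#'
#' Absorption coefficient mu_a (cm^-1) of the pure chromophore at wavelength(s)
#' `lambda` (nm): whole blood (150 g/L haemoglobin, 75% oxygen saturation),
#' water, fat, melanosome interior (`519 * (lambda/500)^-3.5`), and the
#' pigment-free tissue baseline ("other",
#' `0.244 + 85.3 * exp(-(lambda - 154)/66.2)`).
#'
#' @param name One of `"blood"`, `"water"`, `"fat"`, `"melanosome"`, `"other"`.
#' @param lambda Wavelength(s), nm, within 400-1200.
#' @return mu_a in cm^-1, same length as `lambda`.
#' @examples
#' chromophore_mua("melanosome", c(450, 700))
#' @export
chromophore_mua <- function(name, lambda) {
  if (any(lambda < 400 - 1e-9) || any(lambda > 1200 + 1e-9)) {
    stop_subsolar("`lambda` outside the 400-1200 nm support of the bundled spectra.",
                  "subsolar_coverage_error")
  }
  switch(
    match.arg(name, c("blood", "water", "fat", "melanosome", "other")),
    blood = {
      s <- 0.75; conc <- 150 / 64500  # mol/L
      eps <- s * loglin_interp(.hb_tab[c("lambda", "hbo2")], lambda) +
        (1 - s) * loglin_interp(.hb_tab[c("lambda", "hb")], lambda)
      2.303 * eps * conc
    },
    water = loglin_interp(.water_tab, lambda),
    fat = loglin_interp(.fat_tab, lambda),
    melanosome = 519 * (lambda / 500)^(-3.5),
    other = 0.244 + 85.3 * exp(-(lambda - 154) / 66.2)
  )
}

#' Chromophore spectrum from a CSV file
#'
#' Builds a chromophore absorption function from a `wavelength_nm,mua_cm1`
#' table, interpolated log-linearly, for overriding a bundled spectrum.
#'
#' @param path CSV path.
#' @return A function `f(lambda)` returning cm^-1.
#' @export
chromophore_from_csv <- function(path) {
  df <- utils::read.csv(path)
  tab <- data.frame(lambda = as.numeric(df[[1]]), mua = as.numeric(df[[2]]))
  tab <- tab[order(tab$lambda), ]
  lo <- min(tab$lambda); hi <- max(tab$lambda)
  function(lambda) {
    if (any(lambda < lo) || any(lambda > hi)) {
      stop_subsolar("wavelength outside the support of the chromophore CSV.",
                    "subsolar_coverage_error")
    }
    loglin_interp(tab, lambda)
  }
}
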