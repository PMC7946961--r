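Package: subsolar
Title: Predicting the Output Power of Subdermal Solar Modules from Ground Irradiance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the electrical output power of a photovoltaic module implanted
    under human skin, driven by ground-level global-horizontal-irradiance time
    series. The chain runs solar geometry (zenith angle, air mass), an
    air-mass-dependent clear-sky spectral shape scaled to the measured broadband
    irradiance, Monte Carlo photon transport through layered skin (or a measured
    transmission spectrum), an external-quantum-efficiency / open-circuit-voltage
    power model, and daily exposure-profile aggregation into monthly and yearly
    mean-power tables with pacemaker-threshold flags. Includes a seedable
    synthetic-weather generator emulating a minute-resolution radiation station.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
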