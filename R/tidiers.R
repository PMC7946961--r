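# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.transmission_spectrum <- function(x, ...) {
  as_tibble(x)[c("wavelength", "zeta", "stderr")]
}

#' @export
glance.transmission_spectrum <- function(x, ...) {
  tibble(
    n_wavelengths = nrow(x),
    zeta_min = min(x$zeta), zeta_max = max(x$zeta),
    zeta_mean = mean(x$zeta),
    max_stderr = max(x$stderr)
  )
}

#' @export
tidy.power_summary <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"period",
                      names_to = "profile", values_to = "mean_uW")
}

#' @export
glance.power_summary <- function(x, ...) {
  yearly <- tidy.power_summary(x)
  yearly <- yearly[yearly$period == "Full year", ]
  tibble(
    n_profiles = nrow(yearly),
    yearly_min_uW = min(yearly$mean_uW, na.rm = TRUE),
    yearly_max_uW = max(yearly$mean_uW, na.rm = TRUE),
    n_pass_10uW = sum(yearly$mean_uW >= 10, na.rm = TRUE)
  )
}

#' @export
tidy.power_series <- function(x, ...) as_tibble(x)

#' @export
glance.power_series <- function(x, ...) {
  dplyr::group_by(as_tibble(x), .data$profile) |>
    dplyr::summarise(
      n = dplyr::n(),
      exposed_fraction = mean(.data$exposed),
      peak_uW = max(.data$pout_w) * 1e6,
      .groups = "drop"
    )
}

#' @export
autoplot.spectral_irradiance <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression("spectral irradiance" ~ (W ~ m^-2 ~ nm^-1)))
}

#' @export
autoplot.transmission_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength, .data$zeta)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$zeta - 2 * .data$stderr),
                                      ymax = pmin(1, .data$zeta + 2 * .data$stderr)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(zeta ~ "(fraction reaching the implant)"))
}

#' @export
autoplot.radiation_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$timestamp, .data$ghi)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = NULL, y = expression(GHI ~ (W ~ m^-2)))
}

#' @export
autoplot.power_summary <- function(object, threshold = 10, ...) {
  long <- tidy.power_summary(object)
  monthly <- long[long$period != "Full year", ]
  monthly$month <- as.integer(monthly$period)
  ggplot2::ggplot(monthly, ggplot2::aes(.data$month, .data$mean_uW,
                                        colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "month", y = expression(mean ~ power ~ (mu * W)),
                  colour = NULL)
}
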