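#' Plot spectral depth profiles
#'
#' Draws the per-window depth profiles coloured from blue (shortest
#' wavelength) to red (longest), the standard way spectral divergence with
#' depth is visualized.
#'
#' @param profiles long tibble from [spectral_profiles()].
#' @param log_scale plot intensities in dB.
#' @return A ggplot object.
#' @export
plot_spectral_profiles <- function(profiles, log_scale = FALSE) {
  df <- profiles
  if (log_scale) df$intensity <- 10 * log10(pmax(df$intensity, 1e-12))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_um, .data$intensity,
                                   colour = .data$wavelength_nm,
                                   group = .data$wavelength_nm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   name = "wavelength (nm)") +
    ggplot2::labs(x = "depth (µm)",
                  y = if (log_scale) "intensity (dB)" else "intensity") +
    ggplot2::theme_minimal()
}

#' Plot an axial profile
#'
#' @param profile tibble with `depth_um` and `value`.
#' @param ylab y-axis label.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, ylab = "value") {
  ggplot2::ggplot(profile, ggplot2::aes(.data$depth_um, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.trend_fit <- function(object, ...) {
  df <- data.frame(age = object$lm$model$age, y = object$lm$model$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         level = object$conf_level) +
    ggplot2::labs(x = "age (years)", y = object$metric,
                  title = sprintf("%s slope %.3g per year (p = %.3g)",
                                  if (is.na(object$group)) "" else object$group,
                                  object$slope, object$p_slope)) +
    ggplot2::theme_minimal()
}

#' Plot a dilution-series biomarker response
#'
#' @param df tibble with a concentration column and a response column.
#' @param x,y column names.
#' @return A ggplot object with points and a least-squares line.
#' @export
plot_dilution_response <- function(df, x, y) {
  ggplot2::ggplot(df, ggplot2::aes(.data[[x]], .data[[y]])) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dashed") +
    ggplot2::theme_minimal()
}
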