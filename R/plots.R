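# ggplot2 display methods for the package's result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_abline labs scale_x_log10 scale_y_log10 theme_minimal annotate
NULL

#' Plot a radius profile
#'
#' @param object A [radius_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radius_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$z, y = .data$r)) +
    geom_line(colour = "steelblue") +
    labs(x = "z (µm)", y = "r(z) (µm)",
         title = "Axon caliber variation") +
    theme_minimal()
}

#' Plot a structural power spectrum
#'
#' Log-log spectrum; a horizontal low-k plateau diagnoses short-range
#' disorder (structural exponent p = 0).
#'
#' @param object A `power_spectrum` tibble.
#' @param plateau Optional plateau level to annotate (same units as
#'   `gamma`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, plateau = NULL, ...) {
  p <- ggplot(dplyr::filter(object, .data$gamma > 0),
              aes(x = .data$k, y = .data$gamma)) +
    geom_line(colour = "grey40") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "k (rad/µm)",
         y = if (identical(attr(object, "flag"), "of-positions")) {
           expression(Gamma[pos](k))
         } else {
           expression(Gamma[1 * d](k) ~ (mu * m))
         },
         title = "Structural power spectrum") +
    theme_minimal()
  if (!is.null(plateau)) {
    p <- p + geom_hline(yintercept = plateau, linetype = "dashed",
                        colour = "firebrick")
  }
  p
}

#' Plot a power-law fit of D(t)
#'
#' D against `1/sqrt(t)`: the fitted line has intercept `D_inf` and slope
#' `c`; linearity in these coordinates is the short-range-disorder
#' signature.
#'
#' @param object A `powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  df <- object$model$model
  df <- tibble(invsqrt_t = df[[2]], D = df[[1]])
  ggplot(df, aes(x = .data$invsqrt_t, y = .data$D)) +
    geom_point(colour = "steelblue") +
    geom_abline(intercept = object$D_inf, slope = object$c,
                colour = "firebrick") +
    labs(x = expression(1 / sqrt(t) ~ (ms^{-1/2})),
         y = expression(D(t) ~ (mu * m^2 / ms)),
         title = sprintf("D(t) = %.3f + %.3f/√t  (p = %.2g)",
                         object$D_inf, object$c, object$p_slope)) +
    theme_minimal()
}

#' Plot time-dependent cumulants against 1/sqrt(t)
#'
#' @param data A tibble with columns `t` and one of `D` or `K`.
#' @param what Which cumulant column to plot.
#' @return A ggplot.
#' @export
plot_time_dependence <- function(data, what = c("D", "K")) {
  what <- match.arg(what)
  ggplot(data, aes(x = 1 / sqrt(.data$t), y = .data[[what]])) +
    geom_point(colour = "steelblue") + geom_line(colour = "steelblue") +
    labs(x = expression(1 / sqrt(t) ~ (ms^{-1/2})),
         y = if (what == "D") {
           expression(D(t) ~ (mu * m^2 / ms))
         } else {
           expression(K(t))
         }) +
    theme_minimal()
}

#' Plot the zeta versus CV^2 relation
#'
#' @param object A `zeta_result` from [zeta_relation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zeta_result <- function(object, ...) {
  ggplot(object, aes(x = .data$cv2, y = .data$zeta)) +
    geom_point(colour = "steelblue") +
    geom_abline(intercept = attr(object, "intercept"),
                slope = attr(object, "slope"), colour = "firebrick") +
    labs(x = expression(CV^2 * (r)), y = expression(zeta),
         title = sprintf("Pearson R = %.3f", attr(object, "pearson_r"))) +
    theme_minimal()
}
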