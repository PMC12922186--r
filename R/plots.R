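#' @exportS3Method ggplot2::autoplot
autoplot.sas_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$q, y = .data$I)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)")
  if ("sigma" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$I - .data$sigma, .Machine$double.xmin),
                   ymax = .data$I + .data$sigma), alpha = 0.3)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.size_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$size), y = .data$p)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "aggregate size (molecules)",
                  y = "P(molecule in n-aggregate)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.cdf_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$r_mid, y = .data$z_mid,
                               fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~type) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "r (A)", y = "z (A)", fill = expression(rho ~ (ring(A)^-3)))
}

#' @exportS3Method ggplot2::autoplot
autoplot.radial_profile <- function(object, ...) {
  if ("type" %in% names(object)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$density,
                                         colour = .data$type)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "r (A)", y = expression(rho[perp] ~ (ring(A)^-2)))
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$r, y = .data$g)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "r (A)", y = "g(r)")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.mi_refinement <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step,
                                             y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "MC step", y = "metainference energy")
}

#' Plot a fitted model curve over data
#'
#' @param model,data [scattering_curve()]s.
#' @param s,c Scale and offset applied to the model.
#' @return A ggplot.
#' @export
plot_fit <- function(model, data, s = 1, c = 0) {
  df <- dplyr::bind_rows(
    tibble(q = data$q, I = data$I, which = "data"),
    tibble(q = model$q, I = s * model$I + c, which = "model")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$I,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)), y = "I(q) (a.u.)",
                  colour = NULL)
}
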