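#' Plot methods
#'
#' `autoplot()` methods return ggplot objects: the CV trace for a
#' `voltammogram`, peak potentials vs log scan rate (the "trumpet") for
#' `trumpet_data`, data plus fitted curve for a `ph_fit`, and the
#' enthalpy-entropy scatter with regression line(s) for a
#' `compensation_fit`.
#'
#' @param object An object of the corresponding class.
#' @param ... Unused.
#' @return A `ggplot`.
#' @name pfv_plots
NULL

#' @rdname pfv_plots
#' @export
autoplot.voltammogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$potential_V,
                               y = .data$current_A * 1e9,
                               group = .data$segment)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "E (V)", y = "i (nA)",
                  title = sprintf("CV at %g V/s, %g K",
                                  attr(object, "scan_rate"),
                                  attr(object, "temperature")))
}

#' @rdname pfv_plots
#' @export
autoplot.trumpet_data <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           cols = c("E_pa_V", "E_pc_V"),
                           names_to = "peak", values_to = "E_p_V")
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$scan_rate_V_per_s),
                                  y = .data$E_p_V,
                                  shape = .data$peak)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(log[10] ~ nu ~ "(V/s)"), y = "E_p (V)",
                  title = "Trumpet plot")
}

#' @rdname pfv_plots
#' @export
autoplot.ph_fit <- function(object, ...) {
  grid <- tibble::tibble(pH = seq(2, 13, length.out = 300))
  grid$E_V <- eval_ph_model(object$model, grid$pH)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$pH, y = .data$E_V)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "pH", y = "E°' (V)",
                  title = sprintf("Titration fit (%d equilibria)",
                                  object$n_equilibria))
}

#' @rdname pfv_plots
#' @export
autoplot.compensation_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$entropy, y = .data$enthalpy,
                                    colour = .data$outlier)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope) +
    ggplot2::labs(x = expression(Delta * S * minute[rc] ~
                                   "(J mol"^-1 ~ "K"^-1 * ")"),
                  y = expression(Delta * H * minute[rc] ~ "(kJ mol"^-1 * ")"),
                  title = "Enthalpy/entropy compensation")
  if (!is.null(object$refit)) {
    p <- p + ggplot2::geom_abline(intercept = object$refit$intercept,
                                  slope = object$refit$slope,
                                  linetype = "dashed")
  }
  p
}
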