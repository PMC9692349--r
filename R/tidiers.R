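#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per term/parameter,
#' `glance()` one row per fit.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name pfv_tidiers
NULL

#' @rdname pfv_tidiers
#' @export
tidy.redox_thermo <- function(x, ...) {
  tibble::tibble(
    term = c("dE_dT", "entropy", "enthalpy", "gibbs", "E_ref"),
    estimate = c(x$dE_dT, x$entropy, x$enthalpy, x$gibbs, x$E_ref),
    std.error = c(x$dE_dT_se, x$entropy_se, x$enthalpy_se, NA_real_,
                  NA_real_),
    unit = c("V K^-1", "J mol^-1 K^-1", "kJ mol^-1", "kJ mol^-1", "V")
  )
}

#' @rdname pfv_tidiers
#' @export
glance.redox_thermo <- function(x, ...) {
  tibble::tibble(
    condition_label = x$condition_label, E_ref_V = x$E_ref,
    T_ref_K = x$T_ref, entropy_J_mol_K = x$entropy,
    enthalpy_kJ_mol = x$enthalpy, gibbs_kJ_mol = x$gibbs,
    gibbs_from_E_kJ_mol = x$gibbs_from_E
  )
}

#' @rdname pfv_tidiers
#' @export
tidy.ph_fit <- function(x, ...) {
  x$parameters
}

#' @rdname pfv_tidiers
#' @export
glance.ph_fit <- function(x, ...) {
  tibble::tibble(
    n_equilibria = x$n_equilibria, n_obs = x$n_obs, rss = x$rss,
    sigma_V = x$sigma, n_starts = nrow(x$starts),
    n_converged = sum(x$starts$converged), at_bound = x$at_bound
  )
}

#' @rdname pfv_tidiers
#' @export
tidy.et_kinetics <- function(x, ...) {
  tibble::tibble(
    term = c("ks", "alpha"),
    estimate = c(x$ks, x$alpha),
    std.error = c(x$ks_se, NA_real_),
    unit = c("s^-1", "")
  )
}

#' @rdname pfv_tidiers
#' @export
glance.et_kinetics <- function(x, ...) {
  tibble::tibble(
    ks_s1 = x$ks, ks_se_s1 = x$ks_se, alpha = x$alpha,
    method = x$method, temperature_K = x$temperature,
    lower_bound = x$lower_bound, ks_lower_bound_s1 = x$ks_lower_bound
  )
}

#' @rdname pfv_tidiers
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("activation_enthalpy", "slope", "intercept"),
    estimate = c(x$activation_enthalpy, x$slope, x$intercept),
    std.error = c(x$activation_enthalpy_se, NA_real_, NA_real_),
    unit = c("kJ mol^-1", "K", "")
  )
}

#' @rdname pfv_tidiers
#' @export
tidy.compensation_fit <- function(x, ...) {
  x$points
}

#' @rdname pfv_tidiers
#' @export
glance.compensation_fit <- function(x, ...) {
  tibble::tibble(
    slope_K = x$slope, slope_se_K = x$slope_se,
    intercept_kJ_mol = x$intercept, intercept_se_kJ_mol = x$intercept_se,
    r_squared = x$r_squared, n_flagged = sum(x$points$outlier),
    refit_slope_K = if (is.null(x$refit)) NA_real_ else x$refit$slope
  )
}
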