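#' Reduction entropy from the temperature dependence of E°'
#'
#' In a non-isothermal cell the reaction entropy of reduction is read
#' directly from the slope of E°' versus temperature:
#' `dS_rc = S_red - S_ox = n F (dE°'/dT)`, assumed constant over the
#' working range. The slope is an ordinary least-squares fit.
#'
#' @param data A data frame with columns `temperature_K` and `E_V`.
#' @param n Number of electrons.
#' @return A list of class `entropy_fit`: `dE_dT` (V K^-1) and its standard
#'   error, `entropy` (J mol^-1 K^-1) and `entropy_se`, and the underlying
#'   `lm` fit.
#' @export
fit_entropy <- function(data, n = 1L) {
  .check_thermo_table(data)
  fit <- stats::lm(E_V ~ temperature_K, data = data)
  .runs_test_warn(stats::residuals(fit))
  sl <- .lm_summary(fit)$coefficients["temperature_K", ]
  structure(
    list(dE_dT = unname(sl["Estimate"]), dE_dT_se = unname(sl["Std. Error"]),
         entropy = n * pfv_constants$F * unname(sl["Estimate"]),
         entropy_se = n * pfv_constants$F * unname(sl["Std. Error"]),
         n = as.integer(n), fit = fit),
    class = "entropy_fit"
  )
}

#' Reduction enthalpy via the Gibbs-Helmholtz relation
#'
#' Regresses `E°'/T` on `1/T`; the reduction enthalpy is minus `n F` times
#' the slope of that plot, `dH_rc = -n F d(E°'/T)/d(1/T)`.
#'
#' @inheritParams fit_entropy
#' @return A list of class `enthalpy_fit`: `enthalpy` (kJ mol^-1),
#'   `enthalpy_se`, and the underlying `lm` fit.
#' @export
fit_enthalpy <- function(data, n = 1L) {
  .check_thermo_table(data)
  .assert(all(data$temperature_K > 0), "temperatures must be in kelvin (> 0)")
  d <- tibble::tibble(y = data$E_V / data$temperature_K,
                      x = 1 / data$temperature_K)
  fit <- stats::lm(y ~ x, data = d)
  sl <- .lm_summary(fit)$coefficients["x", ]
  structure(
    list(enthalpy = -n * pfv_constants$F * unname(sl["Estimate"]) / 1000,
         enthalpy_se = n * pfv_constants$F * unname(sl["Std. Error"]) / 1000,
         n = as.integer(n), fit = fit),
    class = "enthalpy_fit"
  )
}

# summary.lm warns on zero-residual fits; noiseless synthetic series are a
# legitimate input here, so that specific warning is muffled
.lm_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

.check_thermo_table <- function(data) {
  .assert(is.data.frame(data) && nrow(data) >= 1, "empty table")
  .assert(all(c("temperature_K", "E_V") %in% names(data)),
          "table must have columns `temperature_K` and `E_V`")
  .assert(nrow(data) >= 3, "at least 3 (T, E) points are required")
  .assert(diff(range(data$temperature_K)) >= 10,
          "temperature spread must be at least 10 K")
}

# Wald-Wolfowitz runs test on residual signs; warns on clear lack of fit.
.runs_test_warn <- function(res) {
  s <- sign(res[res != 0])
  n1 <- sum(s > 0); n2 <- sum(s < 0); nn <- n1 + n2
  if (n1 < 2 || n2 < 2 || nn < 8) return(invisible(NULL))
  runs <- 1 + sum(diff(s) != 0)
  mu <- 1 + 2 * n1 * n2 / nn
  v <- 2 * n1 * n2 * (2 * n1 * n2 - nn) / (nn^2 * (nn - 1))
  z <- (runs - mu) / sqrt(v)
  if (stats::pnorm(z) < 0.01) {
    rlang::warn("systematic residual pattern: E(T) may not be linear",
                class = "pfv_lackoffit_warning")
  }
  invisible(NULL)
}

#' Full reduction-thermodynamics summary of an E°'(T) series
#'
#' Combines the entropy and Gibbs-Helmholtz enthalpy fits and evaluates the
#' free energy at the reference temperature. For an ideal linear series the
#' identities `dG = dH - T dS` and `dG = -n F E°'(T_ref)` hold exactly.
#'
#' @inheritParams fit_entropy
#' @param T_ref Reference temperature, K (free energy and `E_ref` are
#'   reported here).
#' @param condition_label Optional label (SAM composition, pH, ...) carried
#'   into compensation analyses.
#' @return An object of class `redox_thermo` with fields `E_ref` (V),
#'   `T_ref`, `dE_dT` (V K^-1), `entropy` (J mol^-1 K^-1), `enthalpy`
#'   (kJ mol^-1), `gibbs` (kJ mol^-1, at `T_ref`), standard errors, and
#'   `condition_label`. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
thermo_summary <- function(data, n = 1L, T_ref = 298.15,
                           condition_label = NA_character_) {
  ent <- fit_entropy(data, n)
  enth <- fit_enthalpy(data, n)
  E_ref <- unname(stats::predict(ent$fit,
                                 tibble::tibble(temperature_K = T_ref)))
  gibbs <- enth$enthalpy - T_ref * ent$entropy / 1000
  structure(
    list(E_ref = E_ref, T_ref = T_ref, n = as.integer(n),
         dE_dT = ent$dE_dT, dE_dT_se = ent$dE_dT_se,
         entropy = ent$entropy, entropy_se = ent$entropy_se,
         enthalpy = enth$enthalpy, enthalpy_se = enth$enthalpy_se,
         gibbs = gibbs,
         gibbs_from_E = -n * pfv_constants$F * E_ref / 1000,
         condition_label = condition_label,
         entropy_fit = ent, enthalpy_fit = enth),
    class = "redox_thermo"
  )
}

#' @export
print.redox_thermo <- function(x, ...) {
  cat(sprintf(
    paste0("<redox_thermo%s> E_ref = %+.4f V at %.2f K\n",
           "  dS_rc = %.1f +/- %.1f J mol^-1 K^-1\n",
           "  dH_rc = %.2f +/- %.2f kJ mol^-1\n",
           "  dG_rc = %.2f kJ mol^-1\n"),
    if (is.na(x$condition_label)) "" else paste0(" ", x$condition_label),
    x$E_ref, x$T_ref, x$entropy, x$entropy_se,
    x$enthalpy, x$enthalpy_se, x$gibbs
  ))
  invisible(x)
}

#' Enthalpy/entropy compensation regression across conditions
#'
#' Regresses the reduction enthalpy on the reduction entropy across a set
#' of conditions (SAM compositions, pH values). Correlated, opposing
#' enthalpy and entropy changes — compensation — show up as a linear trend
#' with free-energy variation smaller than either term. Points whose
#' studentized residual exceeds 2.5 in magnitude are flagged as outliers
#' (conditions where more than solvent reorganization changed), and a refit
#' excluding them is reported when any are flagged.
#'
#' Because a pair of gross outliers can mask each other in ordinary
#' studentized residuals, candidates are first screened against a
#' resistant Theil-Sen line, then refined by backward peeling: the single
#' worst point with |studentized residual| above the cutoff is removed and
#' the line refit until no point exceeds it. Reported studentized
#' residuals are relative to the final clean-subset fit (externally
#' studentized for excluded points).
#'
#' @param thermo A list of `redox_thermo` objects, or a data frame with
#'   columns `entropy` (J mol^-1 K^-1) and `enthalpy` (kJ mol^-1) and
#'   optionally `condition_label`.
#' @param flag_threshold Absolute studentized-residual cutoff (default 2.5).
#' @param refit Refit excluding flagged points (default `TRUE`).
#' @return An object of class `compensation_fit`: the point table with
#'   studentized residuals and outlier flags, slope/intercept with standard
#'   errors, and (when points were flagged and `refit`) the refit line.
#' @export
compensation_regression <- function(thermo, flag_threshold = 2.5,
                                    refit = TRUE) {
  if (is.data.frame(thermo)) {
    d <- tibble::as_tibble(thermo)
    if (!"condition_label" %in% names(d)) d$condition_label <- NA_character_
  } else {
    d <- purrr::map_dfr(thermo, function(t) {
      tibble::tibble(condition_label = t$condition_label,
                     entropy = t$entropy, enthalpy = t$enthalpy)
    })
  }
  .assert(nrow(d) >= 4, "at least 4 conditions are required")
  .assert(stats::sd(d$entropy) > 0,
          "degenerate input: entropy values have zero variance")
  fit <- stats::lm(enthalpy ~ entropy, data = d)
  # initial screen against a resistant Theil-Sen line: a pair of gross
  # outliers can mask each other in plain OLS studentized residuals
  ts <- .theil_sen(d$entropy, d$enthalpy)
  res_ts <- d$enthalpy - ts[1] - ts[2] * d$entropy
  scale_ts <- max(stats::mad(res_ts),
                  1e-8 * stats::sd(d$enthalpy), .Machine$double.eps)
  flag <- abs(res_ts) / scale_ts > flag_threshold
  if (sum(!flag) < 4) flag <- rep(FALSE, nrow(d))
  # backward peeling: flag the single worst |studentized residual| above
  # the cutoff, refit without it, repeat
  repeat {
    if (sum(!flag) < 4) break
    fit_i <- stats::lm(enthalpy ~ entropy, data = d[!flag, , drop = FALSE])
    rs <- stats::rstudent(fit_i)
    rs[!is.finite(rs)] <- 0
    if (max(abs(rs)) <= flag_threshold) break
    flag[which(!flag)[which.max(abs(rs))]] <- TRUE
  }
  # final per-point statistics against the clean-subset fit
  fit_clean <- stats::lm(enthalpy ~ entropy, data = d[!flag, , drop = FALSE])
  s <- .lm_summary(fit_clean)$sigma
  X <- cbind(1, d$entropy[!flag])
  XtXi <- solve(crossprod(X))
  rs_clean <- stats::rstudent(fit_clean)
  rs_clean[!is.finite(rs_clean)] <- 0
  stat <- numeric(nrow(d))
  stat[!flag] <- unname(rs_clean)
  for (i in which(flag)) {
    xi <- c(1, d$entropy[i])
    pred <- sum(xi * stats::coef(fit_clean))
    lev <- drop(t(xi) %*% XtXi %*% xi)
    stat[i] <- (d$enthalpy[i] - pred) / (s * sqrt(1 + lev))
  }
  d$studentized_residual <- stat
  d$outlier <- flag
  .assert(sum(d$outlier) < nrow(d), "all points flagged as outliers")

  co <- .lm_summary(fit)$coefficients
  out <- list(
    points = d,
    slope = co["entropy", "Estimate"], slope_se = co["entropy", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"],
    r_squared = .lm_summary(fit)$r.squared,
    flag_threshold = flag_threshold, fit = fit, refit = NULL
  )
  if (refit && any(d$outlier) && sum(!d$outlier) >= 3) {
    fit2 <- stats::lm(enthalpy ~ entropy, data = d[!d$outlier, ])
    co2 <- .lm_summary(fit2)$coefficients
    out$refit <- list(slope = co2["entropy", "Estimate"],
                      slope_se = co2["entropy", "Std. Error"],
                      intercept = co2["(Intercept)", "Estimate"],
                      intercept_se = co2["(Intercept)", "Std. Error"],
                      r_squared = .lm_summary(fit2)$r.squared, fit = fit2)
  }
  structure(out, class = "compensation_fit")
}

# Theil-Sen resistant line: median pairwise slope, median-based intercept.
.theil_sen <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  sl <- (y[ij[2, ]] - y[ij[1, ]])[dx != 0] / dx[dx != 0]
  b <- stats::median(sl)
  a <- stats::median(y - b * x)
  c(a, b)
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf(
    "<compensation_fit> dH = %.3f * dS %+0.2f kJ mol^-1 (R^2 = %.3f), %d/%d flagged\n",
    x$slope, x$intercept, x$r_squared,
    sum(x$points$outlier), nrow(x$points)
  ))
  invisible(x)
}
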