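# session cache for working curves (keyed by alpha/grid/step)
.pfv_cache <- new.env(parent = emptyenv())

#' Laviron working curve: dimensionless peak separation vs 1/m
#'
#' For a surface-confined couple the peak separation depends on scan rate
#' only through the dimensionless kinetic parameter
#' `m^-1 = (F/(R T)) * nu / ks`. The working curve maps `m^-1` to the
#' dimensionless separation `dEp * F/(R T)`; it is built here by simulating
#' noiseless, capacitance-free surface CVs ([simulate_surface_cv()]) over a
#' grid of `m^-1` and picking peaks, and is cached per session (optionally
#' to a file) because it only depends on `alpha` and the grid.
#'
#' @param alpha Transfer coefficient in (0, 1).
#' @param m_inv Grid of `m^-1` values (positive, increasing). The default
#'   log-spaced grid spans the reversible knee through the fully
#'   irreversible branch.
#' @param potential_step Simulation output resolution, V.
#' @param cache_file Optional path: the curve is read from/written to this
#'   CSV instead of being rebuilt.
#' @return A tibble of class `laviron_curve` with columns `m_inv` and
#'   `delta_ep` (dimensionless), attribute `alpha`.
#' @export
build_working_curve <- function(alpha = 0.5,
                                m_inv = exp(seq(log(0.05), log(300),
                                                length.out = 36)),
                                potential_step = 2e-4,
                                cache_file = NULL) {
  .assert(alpha > 0 && alpha < 1, "`alpha` must lie strictly in (0, 1)")
  .assert(all(m_inv > 0) && !is.unsorted(m_inv),
          "`m_inv` must be positive and increasing")
  key <- paste0("wc_", signif(alpha, 10), "_", length(m_inv), "_",
                signif(m_inv[1], 8), "_", signif(m_inv[length(m_inv)], 8),
                "_", potential_step)
  if (!is.null(.pfv_cache[[key]])) return(.pfv_cache[[key]])
  if (!is.null(cache_file) && file.exists(cache_file)) {
    tab <- utils::read.csv(cache_file)
    out <- structure(tibble::as_tibble(tab),
                     class = c("laviron_curve", class(tibble::tibble())),
                     alpha = alpha)
    .pfv_cache[[key]] <- out
    return(out)
  }

  Tsim <- 298.15
  f <- .f_over_rt(Tsim)
  a_min <- min(alpha, 1 - alpha)
  dep <- vapply(m_inv, function(mi) {
    nu <- mi / f # ks = 1 s^-1
    shift <- max(0, log(max(a_min * mi, 1))) / (a_min * f)
    half <- 0.25 + 1.3 * shift
    cf <- cv_config(formal_potential = 0, ks = 1, alpha = alpha,
                    temperature = Tsim, e_start = -half, e_switch = half,
                    scan_rate = nu, potential_step = potential_step)
    pk <- find_peaks(simulate_surface_cv(cf))
    pk$delta_Ep_V * f
  }, 0)

  out <- structure(
    tibble::tibble(m_inv = m_inv, delta_ep = dep),
    class = c("laviron_curve", class(tibble::tibble())),
    alpha = alpha
  )
  .assert(all(diff(out$delta_ep) > 0),
          "working curve is not strictly increasing; refine the grid")
  .pfv_cache[[key]] <- out
  if (!is.null(cache_file)) utils::write.csv(out, cache_file,
                                             row.names = FALSE)
  out
}

#' Heterogeneous ET rate constant from a trumpet plot (Laviron analysis)
#'
#' `method = "working_curve"` (default) converts each row's peak separation
#' to the dimensionless `m^-1` by inverting the simulated working curve
#' (monotone interpolation in log m^-1), giving a per-row
#' `ks = (F/(R T)) nu / m^-1`; the reported `ks` is the geometric mean and
#' its standard error comes from the spread of the per-row values. Rows
#' whose separation falls below the curve (effectively reversible) carry no
#' kinetic information and are dropped; if every row is reversible
#' (dEp < 5 mV) a lower bound is flagged instead of a point estimate.
#'
#' `method = "irreversible_branch"` uses only rows with
#' `dEp > 200/n mV`, where the branches are linear in log nu:
#' `E_pc - E°' = -(RT/(alpha F)) ln(alpha m^-1)` and the anodic analogue
#' with `1 - alpha`. The transfer coefficient is estimated from both branch
#' slopes and `ks` from the intercept condition `Ep = E°'`.
#'
#' When the working-curve route is used and enough irreversible rows exist,
#' the two estimates are cross-checked and a warning is raised if they
#' disagree by more than 25%.
#'
#' @param trumpet A `trumpet_data` table (see [generate_trumpet_series()]),
#'   or any data frame with columns `scan_rate_V_per_s`, `E_pa_V`, `E_pc_V`
#'   plus a `temperature` attribute/argument.
#' @param method `"working_curve"` or `"irreversible_branch"`.
#' @param alpha Transfer coefficient assumed by the working-curve route
#'   (the paper-style analysis takes 0.5; it is *fitted* only on the
#'   irreversible branch).
#' @param temperature Cell temperature, K; defaults to the table attribute.
#' @param curve Optional pre-built [build_working_curve()] result.
#' @return An object of class `et_kinetics`: `ks` (s^-1), `ks_se`, `alpha`,
#'   `method`, `temperature`, `lower_bound` flag, and the per-row table
#'   `rows`. Has `tidy()`/`glance()` methods.
#' @export
extract_ks <- function(trumpet,
                       method = c("working_curve", "irreversible_branch"),
                       alpha = 0.5, temperature = NULL, curve = NULL) {
  method <- match.arg(method)
  d <- tibble::as_tibble(trumpet)
  .assert(all(c("scan_rate_V_per_s", "E_pa_V", "E_pc_V") %in% names(d)),
          "trumpet table needs scan_rate_V_per_s, E_pa_V, E_pc_V")
  Tk <- temperature %||% attr(trumpet, "temperature")
  .assert(!is.null(Tk) && Tk > 0, "temperature (K) is required")
  n_el <- attr(trumpet, "n_electrons") %||% 1L
  f <- .f_over_rt(Tk) * n_el
  d$delta_Ep_V <- d$E_pa_V - d$E_pc_V

  if (method == "working_curve") {
    res <- .ks_working_curve(d, alpha, f, Tk, curve)
    # opportunistic cross-check on the irreversible branch
    if (!res$lower_bound && sum(d$delta_Ep_V > 0.2 / n_el) >= 3) {
      alt <- tryCatch(.ks_irreversible(d, f, Tk), error = function(e) NULL)
      if (!is.null(alt) && is.finite(alt$ks) &&
          abs(log(alt$ks / res$ks)) > log(1.25)) {
        rlang::warn(sprintf(
          "working-curve and irreversible-branch ks disagree by > 25%% (%.3g vs %.3g s^-1)",
          res$ks, alt$ks), class = "pfv_method_disagreement")
      }
    }
  } else {
    res <- .ks_irreversible(d, f, Tk)
  }
  structure(res, class = "et_kinetics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ks_working_curve <- function(d, alpha, f, Tk, curve) {
  if (is.null(curve)) curve <- build_working_curve(alpha)
  dep <- d$delta_Ep_V * f
  if (all(d$delta_Ep_V < 0.005)) {
    # everything reversible: only a lower bound is identified
    nu_max <- max(d$scan_rate_V_per_s)
    ks_lb <- f * nu_max / min(curve$m_inv)
    return(list(ks = NA_real_, ks_se = NA_real_, alpha = alpha,
                ks_lower_bound = ks_lb, lower_bound = TRUE,
                method = "working_curve", temperature = Tk,
                rows = d))
  }
  usable <- dep >= min(curve$delta_ep) & dep <= max(curve$delta_ep)
  .assert(any(usable),
          "no row falls within the working curve's separation range")
  log_minv <- stats::approx(curve$delta_ep, log(curve$m_inv),
                            xout = dep[usable])$y
  ks_i <- f * d$scan_rate_V_per_s[usable] / exp(log_minv)
  lks <- log(ks_i)
  ks <- exp(mean(lks))
  ks_se <- if (length(lks) > 1) {
    ks * stats::sd(lks) / sqrt(length(lks))
  } else NA_real_
  d$ks_row <- NA_real_
  d$ks_row[usable] <- ks_i
  list(ks = ks, ks_se = ks_se, alpha = alpha, ks_lower_bound = NA_real_,
       lower_bound = FALSE, method = "working_curve", temperature = Tk,
       rows = d)
}

.ks_irreversible <- function(d, f, Tk) {
  thr <- 0.2 * .f_over_rt(Tk) / f # 200/n mV
  ir <- d[d$delta_Ep_V > thr, , drop = FALSE]
  .assert(nrow(ir) >= 3,
          "irreversible-branch method needs >= 3 rows with dEp > 200/n mV")
  E0 <- mean((d$E_pa_V + d$E_pc_V) / 2)
  ln_nu <- log(ir$scan_rate_V_per_s)
  fa <- stats::lm(E_pa_V ~ ln_nu, data = cbind(ir, ln_nu = ln_nu))
  fc <- stats::lm(E_pc_V ~ ln_nu, data = cbind(ir, ln_nu = ln_nu))
  slope_a <- stats::coef(fa)["ln_nu"]
  slope_c <- stats::coef(fc)["ln_nu"]
  .assert(slope_a > 0 && slope_c < 0,
          "irreversible branches have the wrong slope signs")
  one_minus_alpha <- 1 / (f * slope_a)
  alpha_c <- -1 / (f * slope_c)
  alpha <- unname((alpha_c + (1 - one_minus_alpha)) / 2)
  # Ep = E0 at ln nu* ; ks = a_branch * f * nu*
  ln_nu_a <- (E0 - stats::coef(fa)[1]) / slope_a
  ln_nu_c <- (E0 - stats::coef(fc)[1]) / slope_c
  ks_a <- unname(one_minus_alpha * f * exp(ln_nu_a))
  ks_c <- unname(alpha_c * f * exp(ln_nu_c))
  list(ks = sqrt(ks_a * ks_c), ks_se = abs(ks_a - ks_c) / 2,
       alpha = alpha, ks_lower_bound = NA_real_, lower_bound = FALSE,
       method = "irreversible_branch", temperature = Tk,
       rows = d, ks_anodic = ks_a, ks_cathodic = ks_c)
}

#' @export
print.et_kinetics <- function(x, ...) {
  if (x$lower_bound) {
    cat(sprintf("<et_kinetics> reversible at all scan rates: ks > %.3g s^-1 (lower bound)\n",
                x$ks_lower_bound))
  } else {
    cat(sprintf("<et_kinetics> ks = %.3g +/- %.2g s^-1 (alpha = %.2f, %s, T = %g K)\n",
                x$ks, x$ks_se, x$alpha, x$method, x$temperature))
  }
  invisible(x)
}

#' Activation enthalpy from the Arrhenius plot of ks
#'
#' Ordinary least squares of `ln ks` on `1/T`; the activation enthalpy is
#' `-R * slope`. The entropic part of the activation free energy is taken
#' as negligible (so the Arrhenius energy is identified with dH-double-dagger
#' directly, without the RT correction).
#'
#' @param data A data frame with columns `temperature_K` and `ks` (s^-1).
#' @return A list of class `arrhenius_fit`: `activation_enthalpy`
#'   (kJ mol^-1), `activation_enthalpy_se`, `slope` (K), `intercept`
#'   (= ln of the apparent prefactor), and the `lm` fit.
#' @export
arrhenius_activation <- function(data) {
  .assert(all(c("temperature_K", "ks") %in% names(data)),
          "data must have columns `temperature_K` and `ks`")
  .assert(nrow(data) >= 3, "at least 3 temperatures are required")
  .assert(diff(range(data$temperature_K)) >= 15,
          "temperatures must span at least 15 K")
  .assert(all(data$ks > 0), "all ks values must be positive")
  d <- tibble::tibble(y = log(data$ks), x = 1 / data$temperature_K)
  fit <- stats::lm(y ~ x, data = d)
  sl <- .lm_summary(fit)$coefficients["x", ]
  structure(
    list(activation_enthalpy = -pfv_constants$R * unname(sl["Estimate"]) / 1000,
         activation_enthalpy_se = pfv_constants$R * unname(sl["Std. Error"]) / 1000,
         slope = unname(sl["Estimate"]),
         intercept = unname(stats::coef(fit)[1]), fit = fit),
    class = "arrhenius_fit"
  )
}

#' Marcus reorganization energy from the activation enthalpy
#'
#' With a negligible activation entropy the Marcus relation
#' `dG-double-dagger = lambda/4` (zero driving force) inverts to
#' `lambda = 4 dH-double-dagger`. Units are preserved.
#'
#' @param activation_enthalpy Activation enthalpy (>= 0), any energy unit.
#' @return The reorganization energy, same unit.
#' @export
marcus_lambda <- function(activation_enthalpy) {
  .assert(all(activation_enthalpy >= 0),
          "activation enthalpy must be non-negative")
  4 * activation_enthalpy
}

#' Universal ET prefactor kT/h
#'
#' The adiabatic pre-exponential frequency `nu0 = k_B T / h`, about
#' 6e12 s^-1 near room temperature.
#'
#' @param temperature Temperature, K (> 0).
#' @return Frequency in s^-1.
#' @examples
#' prefactor_kT_over_h(290) # ~6.0e12
#' @export
prefactor_kT_over_h <- function(temperature) {
  .assert(all(temperature > 0), "`temperature` must be > 0")
  pfv_constants$k_B * temperature / pfv_constants$h
}

#' Electron-tunneling distance interval from ks and the activation enthalpy
#'
#' Inverts `ln ks = ln nu0 - beta (r - r0) - dH/(R T)` for the tunneling
#' distance `D = r - r0 = (ln nu0 - dH/(R T) - ln ks)/beta`. Because the
#' contact distance r0 is only known to lie in a range (0-3 A by default),
#' the SAM-surface-to-redox-center distance is reported as the interval
#' `D - d_sam + [r0_min, r0_max]`, where `d_sam` is the through-monolayer
#' tunneling distance (about 19 A for an MUA SAM). Negative distances are
#' floored at zero with a warning (redox center inside the SAM is
#' unphysical).
#'
#' @param ks Standard ET rate constant, s^-1 (> 0).
#' @param activation_enthalpy Activation enthalpy, kJ mol^-1.
#' @param temperature Temperature, K.
#' @param nu0 Pre-exponential frequency, s^-1 (default `kT/h` at
#'   `temperature`).
#' @param beta Tunneling decay constant, A^-1 (default 1).
#' @param r0_range Contact-distance range, A (default `c(0, 3)`, within
#'   \[0, 5\]).
#' @param d_sam Through-SAM tunneling distance, A (default 19).
#' @return An object of class `tunneling_estimate` (one-row tibble):
#'   `nu0_s1`, `beta_A1`, `d_sam_A`, `total_distance_minus_r0_A` (D),
#'   `r0_min_A`, `r0_max_A`, `surface_to_center_min_A`,
#'   `surface_to_center_max_A`.
#' @export
tunneling_distance_interval <- function(ks, activation_enthalpy,
                                        temperature = 293.15,
                                        nu0 = prefactor_kT_over_h(temperature),
                                        beta = 1, r0_range = c(0, 3),
                                        d_sam = 19) {
  .assert(ks > 0, "`ks` must be > 0")
  .assert(beta > 0, "`beta` must be > 0")
  .assert(length(r0_range) == 2 && r0_range[1] <= r0_range[2] &&
            r0_range[1] >= 0 && r0_range[2] <= 5,
          "`r0_range` must be an interval within [0, 5] Angstrom")
  dH_J <- activation_enthalpy * 1000
  D <- (log(nu0) - dH_J / (pfv_constants$R * temperature) - log(ks)) / beta
  lo <- D - d_sam + r0_range[1]
  hi <- D - d_sam + r0_range[2]
  if (D < d_sam + r0_range[1]) {
    rlang::warn(paste0(
      "inferred tunneling distance places the redox center inside the ",
      "monolayer (D < d_sam + r0_min); interval floored at 0"
    ), class = "pfv_distance_warning")
  }
  width <- hi - lo
  lo_f <- max(0, lo)
  out <- tibble::tibble(
    nu0_s1 = nu0, beta_A1 = beta, d_sam_A = d_sam,
    total_distance_minus_r0_A = D,
    r0_min_A = r0_range[1], r0_max_A = r0_range[2],
    surface_to_center_min_A = lo_f,
    surface_to_center_max_A = lo_f + width
  )
  class(out) <- c("tunneling_estimate", class(out))
  out
}
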