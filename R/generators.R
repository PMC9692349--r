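#' Synthetic temperature dependence of the formal potential
#'
#' Generates an E°'(T) series as measured in a non-isothermal cell, where
#' the slope dE°'/dT directly reflects the reduction entropy:
#' `E°'(T) = E_ref + (entropy/(n F)) (T - T_ref) + noise`. The reaction
#' entropy is assumed constant over the (narrow) temperature range.
#'
#' @param E_ref Formal potential at `T_ref`, V.
#' @param T_ref Reference temperature, K.
#' @param entropy Reduction entropy `S_red - S_ox`, J mol^-1 K^-1.
#' @param n Number of electrons.
#' @param T_grid Temperatures, K (5-45 C working range).
#' @param noise_sd Gaussian noise on E°', V.
#' @param seed RNG seed for the noise.
#' @return A tibble `(temperature_K, E_V)`; the generating parameters are
#'   attached as attribute `ground_truth`.
#' @export
generate_temperature_series <- function(E_ref, T_ref, entropy, n = 1L,
                                        T_grid = seq(278.15, 318.15, by = 5),
                                        noise_sd = 0, seed = NULL) {
  .assert(length(T_grid) > 0, "empty temperature grid")
  .assert(all(T_grid >= 275 & T_grid <= 322),
          "temperatures must lie in the 5-45 C working range (in kelvin)")
  .assert(noise_sd >= 0, "`noise_sd` must be non-negative")
  E <- E_ref + entropy / (n * pfv_constants$F) * (T_grid - T_ref)
  if (noise_sd > 0) {
    E <- E + with_seed(seed, stats::rnorm(length(T_grid), 0, noise_sd))
  }
  out <- tibble::tibble(temperature_K = T_grid, E_V = E)
  attr(out, "ground_truth") <- list(E_ref = E_ref, T_ref = T_ref,
                                    entropy = entropy, n = n,
                                    noise_sd = noise_sd, seed = seed)
  out
}

#' Synthetic pH dependence of the formal potential
#'
#' Evaluates a redox-linked acid-base titration model ([ph_model()]) on a
#' pH grid and adds Gaussian noise, emulating a formal-potential-vs-pH
#' titration of an immobilized redox protein.
#'
#' @param model A [ph_model()].
#' @param pH_grid Numeric pH values in \[0, 14\].
#' @param noise_sd Gaussian noise on E°', V.
#' @param seed RNG seed for the noise.
#' @return A tibble `(pH, E_V)` with the generating model as attribute
#'   `ground_truth`.
#' @export
generate_ph_series <- function(model, pH_grid, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "ph_model"))
  .assert(length(pH_grid) > 0, "empty pH grid")
  E <- eval_ph_model(model, pH_grid)
  if (noise_sd > 0) {
    E <- E + with_seed(seed, stats::rnorm(length(pH_grid), 0, noise_sd))
  }
  out <- tibble::tibble(pH = pH_grid, E_V = E)
  attr(out, "ground_truth") <- list(model = model, noise_sd = noise_sd,
                                    seed = seed)
  out
}

# Trumpet-data constructor.
new_trumpet_data <- function(data, temperature, formal_potential = NA_real_,
                             n_electrons = 1L, ground_truth = NULL) {
  .assert(nrow(data) >= 4, "trumpet data needs at least 4 scan rates")
  .assert(all(data$scan_rate_V_per_s > 0) &&
            !anyDuplicated(data$scan_rate_V_per_s),
          "scan rates must be positive and distinct")
  out <- tibble::as_tibble(data)
  structure(out,
    class = c("trumpet_data", class(out)),
    temperature = temperature, formal_potential = formal_potential,
    n_electrons = as.integer(n_electrons), ground_truth = ground_truth
  )
}

#' Simulate a trumpet-plot dataset (peak potentials vs scan rate)
#'
#' Runs [simulate_surface_cv()] at each scan rate, picks peaks with
#' [find_peaks()], and tabulates `(nu, E_pa, E_pc)` — the input of the
#' Laviron rate-constant analysis. The sweep window is widened automatically
#' at fast scan rates so the shifted peaks stay inside it.
#'
#' @param config A [cv_config()]; its `scan_rate` field is overridden per
#'   row. Its `rng_seed` seeds the per-rate noise streams.
#' @param scan_rates Scan rates, V s^-1 (>= 4 distinct positive values).
#' @param noise_frac Noise amplitude as a fraction of the reversible-limit
#'   peak current at each rate (overrides `config$noise_sd`).
#' @return A `trumpet_data` tibble
#'   `(scan_rate_V_per_s, E_pa_V, E_pc_V, delta_Ep_V, midpoint_V)` carrying
#'   the ground-truth `ks`, `alpha` and formal potential as attributes.
#' @export
generate_trumpet_series <- function(config, scan_rates, noise_frac = 0) {
  stopifnot(inherits(config, "cv_config"))
  .assert(all(scan_rates > 0), "scan rates must all be positive")
  f <- .f_over_rt(config$temperature)
  a_min <- min(config$alpha, 1 - config$alpha)

  rows <- purrr::map_dfr(seq_along(scan_rates), function(i) {
    nu <- scan_rates[i]
    m_inv <- f * nu / max(config$ks, .Machine$double.eps)
    shift <- max(0, log(max(a_min * m_inv, 1))) / (a_min * f)
    half <- 0.25 + 1.3 * shift
    cf <- cv_config(
      formal_potential = config$formal_potential, ks = config$ks,
      alpha = config$alpha, coverage_total = config$coverage_total,
      electrode_area = config$electrode_area,
      n_electrons = config$n_electrons, temperature = config$temperature,
      e_start = config$formal_potential - half,
      e_switch = config$formal_potential + half,
      scan_rate = nu,
      double_layer_capacitance = config$double_layer_capacitance,
      noise_sd = if (noise_frac > 0) {
        noise_frac * cv_ground_truth(cv_config(
          formal_potential = config$formal_potential,
          coverage_total = config$coverage_total,
          electrode_area = config$electrode_area,
          n_electrons = config$n_electrons,
          temperature = config$temperature, scan_rate = nu
        ))$peak_current_rev
      } else config$noise_sd,
      rng_seed = if (!is.null(config$rng_seed)) config$rng_seed + i else NULL,
      potential_step = config$potential_step
    )
    pk <- find_peaks(simulate_surface_cv(cf))
    tibble::tibble(scan_rate_V_per_s = nu,
                   E_pa_V = pk$E_pa_V, E_pc_V = pk$E_pc_V,
                   delta_Ep_V = pk$delta_Ep_V, midpoint_V = pk$midpoint_V)
  })

  new_trumpet_data(
    rows,
    temperature = config$temperature,
    formal_potential = config$formal_potential,
    n_electrons = config$n_electrons,
    ground_truth = list(ks = config$ks, alpha = config$alpha,
                        formal_potential = config$formal_potential,
                        noise_frac = noise_frac,
                        rng_seed = config$rng_seed)
  )
}
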