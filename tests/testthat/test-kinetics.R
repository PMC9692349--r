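test_that("working curve is strictly increasing and has the right limits", {
  wc <- build_working_curve(alpha = 0.5)
  expect_true(all(diff(wc$delta_ep) > 0))
  # reversible limit: separation vanishes as m^-1 -> 0
  expect_lt(wc$delta_ep[1], 0.2) # < ~5 mV at room temperature
  # irreversible branch slope vs ln(m^-1): d(dEp)/d(ln m^-1) ->
  # 1/alpha + 1/(1-alpha) = 4 at alpha = 0.5
  tail_i <- which(wc$m_inv > 50)
  sl <- coef(lm(wc$delta_ep[tail_i] ~ log(wc$m_inv[tail_i])))[2]
  expect_equal(unname(sl), 4, tolerance = 0.03)
})

test_that("cathodic branch follows the Laviron irreversible closed form", {
  # Epc - E0 = -(RT/alpha F) ln(alpha m^-1) at large m^-1
  f <- 96485.332 / (8.314462 * 293)
  minv <- c(20, 40, 80)
  tr <- generate_trumpet_series(
    cv_config(formal_potential = 0, ks = 1, alpha = 0.5, temperature = 293),
    scan_rates = c(0.5 / f, 1 / f, minv / f)
  )
  d <- tibble::as_tibble(tr)
  ir <- d[d$scan_rate_V_per_s * f >= 20, ]
  pred <- -(1 / (0.5 * f)) * log(0.5 * ir$scan_rate_V_per_s * f)
  expect_lt(max(abs(ir$E_pc_V - pred)), 0.01)
})

test_that("trumpet separation grows with scan rate and ks extraction round-trips", {
  f <- 96485.332 / (8.314462 * 293)
  tr <- generate_trumpet_series(
    cv_config(formal_potential = 0.1, ks = 1, alpha = 0.5,
              temperature = 293),
    scan_rates = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
  )
  expect_true(all(diff(tr$delta_Ep_V) >= -1e-6))
  # fast sweep within the experimental window reaches the
  # irreversible branch
  tr2 <- generate_trumpet_series(
    cv_config(formal_potential = 0, ks = 1, alpha = 0.5,
              temperature = 293),
    scan_rates = c(0.05, 0.1, 0.2, 0.5)
  )
  expect_gt(tr2$delta_Ep_V[4], 0.2)

  # inversion of the curve is the identity on points generated from it
  wc <- build_working_curve(alpha = 0.5)
  ks_true <- 2.7
  pick <- seq(6, 30, by = 6)
  synth <- tibble::tibble(
    scan_rate_V_per_s = wc$m_inv[pick] * ks_true / f,
    E_pa_V = 0.1 + wc$delta_ep[pick] / (2 * f),
    E_pc_V = 0.1 - wc$delta_ep[pick] / (2 * f)
  )
  k <- extract_ks(synth, temperature = 293, curve = wc)
  expect_equal(k$ks, ks_true, tolerance = 0.02)
})

test_that("working-curve and irreversible-branch estimates agree across the kinetic range", {
  f <- 96485.332 / (8.314462 * 293)
  minv <- c(1, 2, 5, 10, 20, 40, 80)
  for (ks in c(0.5, 1, 2, 5)) {
    tr <- generate_trumpet_series(
      cv_config(formal_potential = 0, ks = ks, alpha = 0.5,
                temperature = 293),
      scan_rates = ks * minv / f
    )
    k_wc <- suppressWarnings(extract_ks(tr, method = "working_curve"))
    k_ir <- extract_ks(tr, method = "irreversible_branch")
    expect_equal(k_wc$ks, ks, tolerance = 0.15)
    expect_lt(abs(log(k_wc$ks / k_ir$ks)), log(1.2))
    expect_equal(k_ir$alpha, 0.5, tolerance = 0.1)
  }
})

test_that("ks extraction is invariant to the scan-rate subset", {
  f <- 96485.332 / (8.314462 * 293)
  tr <- generate_trumpet_series(
    cv_config(formal_potential = 0, ks = 1, alpha = 0.5,
              temperature = 293),
    scan_rates = c(1, 2, 5, 10, 20, 40, 80) / f
  )
  d <- tibble::as_tibble(tr)
  k_all <- extract_ks(d, temperature = 293)$ks
  k_low <- extract_ks(d[1:4, ], temperature = 293)$ks
  k_high <- extract_ks(d[4:7, ], temperature = 293)$ks
  expect_lt(abs(log(k_low / k_all)), log(1.05))
  expect_lt(abs(log(k_high / k_all)), log(1.05))
})

test_that("a finer working-curve simulation step barely moves the inverted ks", {
  tr <- generate_trumpet_series(
    cv_config(formal_potential = 0.097, ks = 1, alpha = 0.5,
              temperature = 293),
    scan_rates = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5)
  )
  grid <- exp(seq(log(0.05), log(300), length.out = 24))
  wc1 <- build_working_curve(0.5, m_inv = grid, potential_step = 2e-4)
  wc2 <- build_working_curve(0.5, m_inv = grid, potential_step = 1e-4)
  k1 <- extract_ks(tr, curve = wc1)$ks
  k2 <- extract_ks(tr, curve = wc2)$ks
  expect_lt(abs(k1 / k2 - 1), 0.02)
})

test_that("fully reversible trumpets give a flagged lower bound, not an estimate", {
  wc <- build_working_curve(alpha = 0.5)
  synth <- tibble::tibble(
    scan_rate_V_per_s = c(0.02, 0.05, 0.1, 0.2),
    E_pa_V = 0.1 + c(0.2, 0.5, 1, 2) * 1e-3,
    E_pc_V = 0.1 - c(0.2, 0.5, 1, 2) * 1e-3
  )
  k <- extract_ks(synth, temperature = 293, curve = wc)
  expect_true(k$lower_bound)
  expect_true(is.na(k$ks))
  expect_gt(k$ks_lower_bound, 0)
})

test_that("Arrhenius slope yields the activation enthalpy", {
  Tg <- seq(278.15, 318.15, by = 5)
  # constant ks -> zero activation enthalpy
  d0 <- tibble::tibble(temperature_K = Tg, ks = rep(2, length(Tg)))
  expect_equal(arrhenius_activation(d0)$activation_enthalpy, 0,
               tolerance = 1e-9)
  # ks = exp(29.42 - 2700/T) -> dH = 2700 R = 22.4 kJ/mol
  d1 <- tibble::tibble(temperature_K = Tg, ks = exp(29.42 - 2700 / Tg))
  a1 <- arrhenius_activation(d1)
  expect_equal(a1$activation_enthalpy, 2700 * 8.314462 / 1000,
               tolerance = 1e-6)
  expect_equal(a1$activation_enthalpy, 22.4, tolerance = 1e-2)
  # 5% relative noise, seeded: recovery within 2 SE
  set.seed(13)
  d2 <- tibble::tibble(temperature_K = Tg,
                       ks = exp(29.42 - 2700 / Tg) * exp(rnorm(length(Tg),
                                                               0, 0.05)))
  a2 <- arrhenius_activation(d2)
  expect_lt(abs(a2$activation_enthalpy - 22.449),
            2 * a2$activation_enthalpy_se)
  expect_error(arrhenius_activation(
    tibble::tibble(temperature_K = Tg, ks = -1)))
})

test_that("Marcus relation and prefactor behave as closed forms", {
  expect_equal(marcus_lambda(0), 0)
  expect_equal(marcus_lambda(22.4), 89.6)
  expect_error(marcus_lambda(-1))
  expect_equal(signif(prefactor_kT_over_h(290), 2), 6.0e12)
  expect_equal(prefactor_kT_over_h(298.15),
               1.380649e-23 * 298.15 / 6.62607e-34)
  # linear in T
  expect_equal(prefactor_kT_over_h(580), 2 * prefactor_kT_over_h(290))
})

test_that("tunneling-distance interval follows the Marcus distance decay", {
  # ks = 1, dH = 0, nu0 = 6e12, beta = 1: D = ln(6e12) = 29.4 A
  te <- tunneling_distance_interval(1, 0, temperature = 293, nu0 = 6e12)
  expect_equal(te$total_distance_minus_r0_A, log(6e12), tolerance = 1e-9)
  expect_equal(te$total_distance_minus_r0_A, 29.4, tolerance = 1e-2)

  # reverse-engineered combination: ln nu0 - dH/RT - ln ks = 20.1,
  # d_sam = 19, r0 in [0, 3] -> surface-to-center interval [1.1, 4.1] A
  Tk <- 293.15
  ks <- exp(log(6e12) - 20.1)
  te2 <- tunneling_distance_interval(ks, 0, temperature = Tk, nu0 = 6e12)
  expect_equal(te2$surface_to_center_min_A, 1.1, tolerance = 1e-6)
  expect_equal(te2$surface_to_center_max_A, 4.1, tolerance = 1e-6)

  # interval width always equals the r0 range width
  for (ks_i in c(0.1, 1, 50)) {
    t_i <- suppressWarnings(
      tunneling_distance_interval(ks_i, 10, temperature = 300)
    )
    expect_equal(t_i$surface_to_center_max_A - t_i$surface_to_center_min_A,
                 3, tolerance = 1e-12)
  }
  # unphysical placement warns and floors at zero
  expect_warning(
    tunneling_distance_interval(1e9, 20, temperature = 293),
    class = "pfv_distance_warning"
  )
  expect_error(tunneling_distance_interval(-1, 0))
  expect_error(tunneling_distance_interval(1, 0, r0_range = c(0, 7)))
})
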