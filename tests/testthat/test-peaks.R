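test_that("baseline correction removes linear backgrounds", {
  # capacitive-only CV: corrected current ~ 0 everywhere
  vg <- simulate_surface_cv(quasi_config(coverage_total = 1e-18,
                                         double_layer_capacitance = 2e-5))
  bc <- suppressWarnings(baseline_correct(vg, "anodic"))
  expect_lt(max(abs(bc$current_corrected_A)), 1e-12)

  # flat zero current: zero baseline, zero corrected
  vg0 <- simulate_surface_cv(quasi_config(coverage_total = 1e-18))
  bc0 <- suppressWarnings(baseline_correct(vg0, "cathodic"))
  expect_lt(max(abs(bc0$current_corrected_A)), 1e-13)
  expect_lt(max(abs(attr(bc0, "coefficients"))), 1e-12)

  # surface wave on a known linear background: peak current recovered
  vg1 <- simulate_surface_cv(quasi_config(ks = 1e5,
                                          double_layer_capacitance = 2e-5))
  pk <- find_peaks(vg1)
  gt <- attr(vg1, "ground_truth")
  expect_equal(pk$i_pa_A, gt$peak_current_rev, tolerance = 0.005)
})

test_that("find_peaks recovers the configured formal potential", {
  pk <- find_peaks(simulate_surface_cv(quasi_config()))
  expect_lt(abs(pk$midpoint_V - 0.097), 0.002)
  expect_gte(pk$delta_Ep_V, 0)
  expect_equal(pk$midpoint_V, (pk$E_pa_V + pk$E_pc_V) / 2)
})

test_that("anodic and cathodic peak areas balance for a reversible couple", {
  pk <- find_peaks(simulate_surface_cv(quasi_config(ks = 1e5)))
  expect_equal(pk$Q_a_C / pk$Q_c_C, 1, tolerance = 0.01)
})

test_that("degenerate and featureless inputs raise no-peak errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# scan_rate_V_per_s: 0.05", "# temperature_K: 293",
               "potential_V,current_A", "0,1e-9", "0.1,2e-9"), path)
  expect_error(find_peaks(read_voltammogram(path)),
               class = "pfv_no_peak_error")
  # flat trace: no extremum above the noise floor
  flat <- simulate_surface_cv(quasi_config(coverage_total = 1e-18,
                                           noise_sd = 1e-11, rng_seed = 5))
  expect_error(find_peaks(flat), class = "pfv_no_peak_error")
})

test_that("surface coverage follows Q/(nFA) and is scan-rate invariant", {
  # closed-form check
  vg <- simulate_surface_cv(quasi_config())
  pk <- find_peaks(vg)
  cov <- surface_coverage(pk, vg)
  expect_equal(cov$gamma0_mol_cm2,
               pk$Q_c_C / (96485.332 * 0.1), tolerance = 1e-12)

  # recovery of the simulated coverage within 2% across the kinetic range
  for (ks in c(0.5, 2, 10)) {
    vg <- simulate_surface_cv(quasi_config(ks = ks,
                                           coverage_total = 5e-12))
    cov <- surface_coverage(find_peaks(vg), vg)
    expect_equal(cov$gamma0_mol_cm2, 5e-12, tolerance = 0.02)
  }

  # doubling the scan rate leaves the coverage unchanged
  v1 <- simulate_surface_cv(quasi_config(scan_rate = 0.05))
  v2 <- simulate_surface_cv(quasi_config(scan_rate = 0.1))
  g1 <- surface_coverage(find_peaks(v1), v1)$gamma0_mol_cm2
  g2 <- surface_coverage(find_peaks(v2), v2)$gamma0_mol_cm2
  expect_equal(g1, g2, tolerance = 0.02)
})

test_that("Randles-Sevcik area calibration is self-consistent and scales correctly", {
  Fc <- 96485.332; Rc <- 8.314462
  A_true <- 0.05; n <- 1; C <- 1e-6; D <- 1e-5; nu <- 0.1; Tk <- 298.15
  ip <- 0.4463 * n * Fc * A_true * C * sqrt(n * Fc * nu * D / (Rc * Tk))
  expect_equal(electrode_area_randles_sevcik(ip, C, D, nu, n, Tk), A_true,
               tolerance = 1e-12)
  # linear in i_p
  expect_equal(electrode_area_randles_sevcik(2 * ip, C, D, nu, n, Tk),
               2 * A_true, tolerance = 1e-12)
  # nu quadrupled at fixed i_p halves the area
  expect_equal(electrode_area_randles_sevcik(ip, C, D, 4 * nu, n, Tk),
               A_true / 2, tolerance = 1e-12)
  expect_error(electrode_area_randles_sevcik(-ip, C, D, nu))
})

test_that("reference-scale conversion applies the SCE offset both ways", {
  expect_equal(convert_reference(0, "SCE", "SHE"), 0.2412)
  expect_equal(convert_reference(convert_reference(0.1, "SCE", "SHE"),
                                 "SHE", "SCE"), 0.1)
  expect_equal(convert_reference(0.3, "SHE", "SHE"), 0.3)
  expect_error(convert_reference(0, "AgCl", "SHE"))
})

test_that("pipeline linearity: i_p vs nu regression on processed CVs", {
  nus <- c(0.02, 0.05, 0.1, 0.2)
  ip <- vapply(nus, function(nu) {
    find_peaks(simulate_surface_cv(quasi_config(ks = 1e5,
                                                scan_rate = nu)))$i_pa_A
  }, 0)
  r2 <- suppressWarnings(summary(lm(ip ~ nus))$r.squared)
  expect_gt(r2, 0.999)
})
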