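test_that("titration model has the correct limits, span, and monotonicity", {
  m <- enzyme_ph_model()
  # acid limit
  expect_equal(eval_ph_model(m, 2), m$E_lowpH, tolerance = 2e-4)
  # alkaline limit: E_lowpH - c * sum(pKa_red - pKa_ox) = E_lowpH - 0.059*7.3
  span <- m$nernst_coefficient * sum(m$pka_red - m$pka_ox)
  expect_equal(span, 0.059 * 7.3, tolerance = 1e-12)
  H <- 10^(-14)
  alk <- m$E_lowpH + m$nernst_coefficient *
    sum(log10((10^(-m$pka_red) + H) / (10^(-m$pka_ox) + H)))
  expect_lt(abs(alk - (m$E_lowpH - 0.431)), 1e-3)
  # non-increasing in pH for random valid models
  set.seed(1)
  for (r in 1:20) {
    k <- sample(1:3, 1)
    pko <- sort(runif(k, 2.5, 10))
    m_r <- ph_model(0.1, pko, pko + runif(k, 0.2, 2.5))
    E <- eval_ph_model(m_r, seq(0, 14, by = 0.1))
    expect_true(all(diff(E) <= 1e-12))
  }
})

test_that("mid-region behaviour matches the one-proton linear regime", {
  # well-separated single equilibrium: slope -2.303RT/F at 293 K (~ -58 mV)
  c293 <- 2.303 * 8.314462 * 293 / 96485.332
  m1 <- ph_model(0.1, 4, 12, nernst_coefficient = c293)
  expect_equal(1000 * local_slope(m1, 8), -58.2, tolerance = 0.01)
  # value in the linear regime: E_lowpH + c (pKa_ox - pH)
  expect_equal(eval_ph_model(m1, 8), 0.1 + c293 * (4 - 8), tolerance = 1e-4)
  # far from all pKa's the slope vanishes
  m <- enzyme_ph_model()
  expect_lt(abs(local_slope(m, 2)), 1e-4)
  # two fully-overlapping equilibria in regime: slope -2c
  m2 <- ph_model(0.1, c(4, 4.0001), c(12, 12.0001))
  expect_equal(local_slope(m2, 8), -2 * 0.059, tolerance = 1e-3)
})

test_that("analytic slope agrees with central differences", {
  m <- enzyme_ph_model()
  h <- 1e-6
  for (pH in seq(3, 13, by = 0.5)) {
    num <- (eval_ph_model(m, pH + h) - eval_ph_model(m, pH - h)) / (2 * h)
    expect_lt(abs(local_slope(m, pH) - num), 1e-9)
  }
})

test_that("apparent proton uptake matches the titration fractions", {
  m <- enzyme_ph_model()
  # plateaus
  expect_lt(proton_uptake(m, 2.5), 0.05)
  # one proton lost across the first equilibrium
  u1 <- proton_uptake(m, 6.3)
  expect_gt(u1, 0.8); expect_lt(u1, 1.0)
  # approaching two protons across the overlapping pair
  u2 <- proton_uptake(m, 9.8)
  expect_gt(u2, 1.4); expect_lt(u2, 2.0)
  # bounded by the number of equilibria
  expect_true(all(proton_uptake(m, seq(0, 14, 0.25)) <= 3))
  expect_error(eval_ph_model(m, 14.5))
})

test_that("noiseless single-equilibrium data are recovered exactly", {
  m <- ph_model(0.25, 6, 9)
  d <- generate_ph_series(m, seq(3.5, 11.5, by = 0.5))
  fit <- fit_ph_model(d, n_equilibria = 1, n_starts = 20, seed = 2)
  expect_equal(fit$model$E_lowpH, 0.25, tolerance = 1e-6)
  expect_equal(fit$model$pka_ox, 6, tolerance = 1e-5)
  expect_equal(fit$model$pka_red, 9, tolerance = 1e-5)
  expect_lt(fit$sigma, 1e-6)
})

test_that("three-equilibria recovery from noisy data hits the generating constants", {
  d <- generate_ph_series(enzyme_ph_model(), seq(4, 12, by = 0.25),
                          noise_sd = 0.002, seed = 7)
  fit <- fit_ph_model(d, n_equilibria = 3, n_starts = 50, seed = 11)
  p <- fit$parameters
  est <- function(term) p$estimate[p$term == term]
  expect_lt(abs(est("pKa1ox") - 5.1), 0.3)
  expect_lt(abs(est("pKa1red") - 7.5), 0.3)
  expect_lt(abs(est("pKa2red") - 10.9), 0.5)
  expect_true(all(fit$model$pka_red > fit$model$pka_ox))
  # the multi-start record honours its invariant
  expect_lte(fit$rss, min(fit$starts$objective[fit$starts$converged]) + 1e-12)
})

test_that("bootstrap standard errors for the overlapping pair are reported", {
  d <- generate_ph_series(enzyme_ph_model(), seq(4, 12, by = 0.25),
                          noise_sd = 0.002, seed = 7)
  fit <- fit_ph_model(d, n_equilibria = 3, n_starts = 10, seed = 11,
                      n_boot = 25)
  expect_true("boot.std.error" %in% names(fit$parameters))
  se23 <- fit$parameters$boot.std.error[
    fit$parameters$term %in% c("pKa2red", "pKa3red")]
  expect_true(all(is.finite(se23)))
  expect_true(all(se23 > 0))
})

test_that("model-size selection behaves on constructed datasets", {
  # 1-equilibrium data select 1
  d1 <- generate_ph_series(ph_model(0.2, 6, 9), seq(3.5, 11.5, by = 0.5),
                           noise_sd = 0.002, seed = 3)
  s1 <- select_n_equilibria(d1, n_starts = 15, seed = 4)
  expect_identical(s1$selected, 1L)
  # 3-equilibria data (overlapping pair): at least 2 selected
  d3 <- generate_ph_series(enzyme_ph_model(), seq(4, 12, by = 0.25),
                           noise_sd = 0.002, seed = 5)
  s3 <- select_n_equilibria(d3, n_starts = 25, seed = 6)
  expect_gte(s3$selected, 2L)
  # constant data: smallest model, parameters at bounds flagged
  dc <- tibble::tibble(pH = seq(4, 12, by = 0.5), E_V = 0.15)
  sc <- select_n_equilibria(dc, n_starts = 10, seed = 8)
  expect_identical(sc$selected, 1L)
  expect_true(sc$table$at_bound[1])
})

test_that("fit preconditions and pathological inputs error cleanly", {
  d <- generate_ph_series(ph_model(0.2, 6, 9), seq(5, 7, by = 0.5))
  expect_error(fit_ph_model(d, n_equilibria = 1), "span")
  expect_error(ph_model(0.1, 7, 6))
  expect_error(ph_model(0.1, 1, 9))
  expect_error(ph_model(0.1, c(5, 6), 8))
  expect_error(generate_ph_series(ph_model(0.1, 5, 8), c(3, 15)))
})
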