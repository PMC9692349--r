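# shared fixtures and independent oracles

# quasi-reversible default: the immobilized-enzyme regime
quasi_config <- function(...) {
  args <- list(...)
  base <- list(formal_potential = 0.097, ks = 1, alpha = 0.5,
               temperature = 293, scan_rate = 0.05,
               coverage_total = 1e-11, electrode_area = 0.1)
  do.call(cv_config, utils::modifyList(base, args))
}

# FWHM of a baseline-corrected anodic wave, linear interpolation at the
# half-height crossings
measure_fwhm <- function(vg) {
  bc <- baseline_correct(vg, "anodic")
  y <- bc$current_corrected_A
  x <- bc$potential_V
  half <- max(y) / 2
  above <- which(y > half)
  i1 <- above[1]; i2 <- above[length(above)]
  xl <- x[i1 - 1] + (half - y[i1 - 1]) / (y[i1] - y[i1 - 1]) *
    (x[i1] - x[i1 - 1])
  xr <- x[i2] + (half - y[i2]) / (y[i2 + 1] - y[i2]) *
    (x[i2 + 1] - x[i2])
  abs(xr - xl)
}

# Independent oracle: naive explicit (forward-Euler) integration of the
# surface Butler-Volmer site balance at a fine fixed time step. Shares no
# code with the package integrator.
oracle_surface_cv <- function(E0, ks, alpha, temperature, scan_rate,
                              e_start, e_switch, dt = NULL) {
  f <- 96485.332 / (8.314462 * temperature)
  if (is.null(dt)) {
    b_max <- 2 * ks * exp(max(alpha, 1 - alpha) * f *
                            max(abs(c(e_start, e_switch) - E0)))
    dt <- min(1e-4 / scan_rate, 0.05 / b_max)
  }
  sweep <- function(ea, eb, x0, dir) {
    tt <- seq(0, abs(eb - ea) / scan_rate, by = dt)
    E <- ea + dir * scan_rate * tt
    x <- numeric(length(tt)); x[1] <- x0
    for (i in seq_len(length(tt) - 1)) {
      kox <- ks * exp((1 - alpha) * f * (E[i] - E0))
      kred <- ks * exp(-alpha * f * (E[i] - E0))
      x[i + 1] <- x[i] + dt * (kox * (1 - x[i]) - kred * x[i])
    }
    list(E = E, x = x, dxdt = c(diff(x) / dt, NA))
  }
  d1 <- sign(e_switch - e_start)
  s1 <- sweep(e_start, e_switch, 1 / (1 + exp(-f * (e_start - E0))), d1)
  s2 <- sweep(e_switch, e_start, s1$x[length(s1$x)], -d1)
  ep_a <- if (d1 > 0) s1$E[which.max(s1$dxdt)] else s2$E[which.max(s2$dxdt)]
  ep_c <- if (d1 > 0) s2$E[which.min(s2$dxdt)] else s1$E[which.min(s1$dxdt)]
  list(E_pa = ep_a, E_pc = ep_c, delta_Ep = ep_a - ep_c)
}

# the three redox-linked acid-base equilibria of the covalently bound
# enzyme (acid-limit potential arbitrary)
enzyme_ph_model <- function(E_lowpH = 0.132) {
  ph_model(E_lowpH, c(5.1, 8.4, 8.9), c(7.5, 10.9, 11.3))
}

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
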