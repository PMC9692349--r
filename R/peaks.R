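# Trapezoidal integral of y over x.
.trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# Split a voltammogram into sweep segments, each tagged with its direction
# ("anodic" = potential increasing, "cathodic" = decreasing).
cv_segments <- function(vg) {
  seg_ids <- if ("segment" %in% names(vg)) unique(vg$segment) else {
    split_idx <- .detect_split(vg$potential_V)
    vg$segment <- rep(2L, nrow(vg))
    if (!is.na(split_idx)) vg$segment[seq_len(split_idx)] <- 1L else
      vg$segment[] <- 1L
    unique(vg$segment)
  }
  out <- lapply(seg_ids, function(s) {
    d <- vg[vg$segment == s, , drop = FALSE]
    dir <- if (utils::tail(d$potential_V, 1) > d$potential_V[1]) "anodic"
           else "cathodic"
    attr(d, "direction") <- dir
    d
  })
  names(out) <- vapply(out, attr, "", "direction")
  out
}

#' Linear baseline correction of one sweep segment
#'
#' Fits a least-squares straight line through the two flanking windows of a
#' sweep segment (each spanning `flank_fraction` of the segment length) and
#' subtracts it, isolating the faradaic peak from the capacitive/residual
#' background — the standard pre-processing step before integrating protein
#' film peaks.
#'
#' @param vg A `voltammogram`.
#' @param segment `"anodic"` or `"cathodic"`: which sweep to correct.
#' @param flank_fraction Fraction of the segment length used for each flank
#'   window; in (0, 0.25].
#' @return A tibble `(potential_V, current_A, current_corrected_A)` with the
#'   baseline `coefficients` (intercept, slope) and the flank indices as
#'   attributes.
#' @export
baseline_correct <- function(vg, segment = c("anodic", "cathodic"),
                             flank_fraction = 0.1) {
  segment <- match.arg(segment)
  .assert(flank_fraction > 0 && flank_fraction <= 0.25,
          "`flank_fraction` must lie in (0, 0.25]")
  segs <- cv_segments(vg)
  .assert(segment %in% names(segs),
          paste0("voltammogram has no ", segment, " segment"))
  d <- segs[[segment]]
  n <- nrow(d)
  .assert(n >= 8, "segment too short for baseline correction",
          class = "pfv_no_peak_error")
  k <- max(2L, floor(n * flank_fraction))
  flank <- c(seq_len(k), seq.int(n - k + 1L, n))
  fit <- stats::lm.fit(cbind(1, d$potential_V[flank]), d$current_A[flank])
  baseline <- fit$coefficients[1] + fit$coefficients[2] * d$potential_V
  corrected <- d$current_A - baseline

  peak_idx <- if (segment == "anodic") which.max(corrected)
              else which.min(corrected)
  if (peak_idx %in% flank) {
    rlang::warn(paste0(
      "apparent peak lies inside a baseline flank window; consider a ",
      "smaller `flank_fraction`"
    ), class = "pfv_flank_warning")
  }
  out <- tibble::tibble(potential_V = d$potential_V,
                        current_A = d$current_A,
                        current_corrected_A = corrected)
  attr(out, "coefficients") <- stats::setNames(fit$coefficients,
                                               c("intercept", "slope"))
  attr(out, "flank_index") <- flank
  attr(out, "direction") <- segment
  out
}

#' Locate anodic and cathodic peaks of a cyclic voltammogram
#'
#' Baseline-corrects each sweep segment, locates the anodic maximum and
#' cathodic minimum of the corrected current with parabolic sub-grid
#' refinement (least-squares quadratic over a small window around the raw
#' extremum), and integrates the corrected current over the peak support —
#' bounded by the zero crossings of the corrected current, falling back to a
#' fixed +/-150 mV window — to obtain the exchanged charges
#' `Q = |int i dE| / nu`. The formal (midpoint) potential is the semi-sum
#' of the two peak potentials.
#'
#' @param vg A `voltammogram` containing both sweep segments.
#' @param flank_fraction Passed to [baseline_correct()].
#' @return A one-row tibble of class `peakset`:
#'   `E_pa_V`, `E_pc_V`, `i_pa_A`, `i_pc_A` (baseline-corrected),
#'   `Q_a_C`, `Q_c_C`, `delta_Ep_V = E_pa - E_pc`,
#'   `midpoint_V = (E_pa + E_pc)/2`. Baseline coefficients per segment are
#'   attached as attribute `baselines`.
#' @export
find_peaks <- function(vg, flank_fraction = 0.1) {
  stopifnot(inherits(vg, "voltammogram"))
  .assert(nrow(vg) >= 8, "no peak found: too few points",
          class = "pfv_no_peak_error")
  segs <- cv_segments(vg)
  .assert(all(c("anodic", "cathodic") %in% names(segs)),
          "both sweep segments are required", class = "pfv_no_peak_error")
  nu <- attr(vg, "scan_rate")

  an <- .segment_peak(baseline_correct(vg, "anodic", flank_fraction),
                      sign = +1, nu = nu)
  ca <- .segment_peak(baseline_correct(vg, "cathodic", flank_fraction),
                      sign = -1, nu = nu)

  out <- tibble::tibble(
    E_pa_V = an$E_p, E_pc_V = ca$E_p,
    i_pa_A = an$i_p, i_pc_A = ca$i_p,
    Q_a_C = an$Q, Q_c_C = ca$Q,
    delta_Ep_V = an$E_p - ca$E_p,
    midpoint_V = (an$E_p + ca$E_p) / 2
  )
  attr(out, "baselines") <- list(anodic = an$baseline,
                                 cathodic = ca$baseline)
  class(out) <- c("peakset", class(out))
  out
}

# Peak location, height and charge for one baseline-corrected segment.
# `sign = +1` anodic (maximum), -1 cathodic (minimum).
.segment_peak <- function(bc, sign, nu) {
  y <- sign * bc$current_corrected_A
  x <- bc$potential_V
  n <- length(y)
  flank <- attr(bc, "flank_index")

  # light smoothing for index location and support detection only
  k <- max(3L, 2L * floor(n / 200) + 1L)
  ys <- if (n > 2 * k) stats::filter(y, rep(1 / k, k), sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  idx <- which.max(ys)

  noise_floor <- 3 * stats::mad(bc$current_corrected_A[flank])
  if (!(ys[idx] > noise_floor) || idx %in% c(1L, n)) {
    rlang::abort(
      "no peak found: no extremum above the flank noise floor",
      class = "pfv_no_peak_error"
    )
  }

  # parabolic refinement: least-squares quadratic around the raw extremum
  hw <- max(2L, min(floor(n / 20), 40L))
  win <- max(1L, idx - hw):min(n, idx + hw)
  qf <- stats::lm.fit(cbind(1, x[win] - x[idx], (x[win] - x[idx])^2), y[win])
  cc <- unname(qf$coefficients)
  E_p <- x[idx]; i_p <- unname(y[idx])
  if (is.finite(cc[3]) && cc[3] < 0) {
    dx <- -cc[2] / (2 * cc[3])
    if (abs(dx) <= abs(x[win[length(win)]] - x[idx])) {
      E_p <- x[idx] + dx
      i_p <- cc[1] - cc[2]^2 / (4 * cc[3])
    }
  }

  # peak support: zero crossings of the (smoothed) corrected current,
  # falling back to a fixed 150 mV half-window where a crossing is absent
  left <- idx; right <- idx
  while (left > 1L && ys[left] > 0) left <- left - 1L
  while (right < n && ys[right] > 0) right <- right + 1L
  dx_dir <- sign(x[n] - x[1])
  if (left == 1L && ys[1] > 0) {
    left <- which.min(abs(x - (x[idx] - 0.15 * dx_dir)))
  }
  if (right == n && ys[n] > 0) {
    right <- which.min(abs(x - (x[idx] + 0.15 * dx_dir)))
  }
  support <- min(left, idx):max(right, idx)
  Q <- abs(.trapz(x[support], bc$current_corrected_A[support])) / nu

  list(E_p = E_p, i_p = sign * i_p, Q = Q,
       baseline = attr(bc, "coefficients"))
}

#' Electroactive surface coverage from the exchanged charge
#'
#' Converts the baseline-corrected cathodic peak charge into the surface
#' coverage of electroactive protein, `Gamma_0 = Q_c / (n F A)` — the
#' integrated-peak relation `int i(E) dE = nu n F A Gamma_0` for a
#' diffusionless couple. The cathodic charge is used as the estimator; the
#' anodic charge is retained upstream for the peak-area-ratio diagnostic.
#'
#' @param peaks A `peakset` from [find_peaks()].
#' @param vg The source `voltammogram` (provides area, n, scan rate).
#' @return A one-row tibble: `gamma0_mol_cm2`, `Q_tot_C`, `area_cm2`,
#'   `n_electrons`, `scan_rate_V_per_s`.
#' @export
surface_coverage <- function(peaks, vg) {
  stopifnot(inherits(peaks, "peakset"), inherits(vg, "voltammogram"))
  A <- attr(vg, "electrode_area")
  n <- attr(vg, "n_electrons")
  .assert(is.finite(A) && A > 0,
          "electrode area must be present and positive")
  .assert(is.finite(n) && n >= 1, "n_electrons must be present")
  tibble::tibble(
    gamma0_mol_cm2 = peaks$Q_c_C / (n * pfv_constants$F * A),
    Q_tot_C = peaks$Q_c_C,
    area_cm2 = A,
    n_electrons = as.integer(n),
    scan_rate_V_per_s = attr(vg, "scan_rate")
  )
}

#' Electrode area from the Randles-Sevcik relation
#'
#' Electrochemical area calibration from the diffusion-limited peak current
#' of a reversible solution couple of known concentration and diffusion
#' coefficient: `i_p = 0.4463 n F A C sqrt(n F nu D / (R T))`, solved
#' for A.
#'
#' @param peak_current Peak current, A.
#' @param concentration Bulk concentration, mol cm^-3.
#' @param diffusion_coefficient Diffusion coefficient, cm^2 s^-1.
#' @param scan_rate Scan rate, V s^-1.
#' @param n Number of electrons.
#' @param temperature Temperature, K.
#' @return Electrode area in cm^2.
#' @export
electrode_area_randles_sevcik <- function(peak_current, concentration,
                                          diffusion_coefficient, scan_rate,
                                          n = 1L, temperature = 298.15) {
  .assert(all(c(peak_current, concentration, diffusion_coefficient,
                scan_rate, n, temperature) > 0),
          "all Randles-Sevcik inputs must be positive")
  Fc <- pfv_constants$F; Rc <- pfv_constants$R
  peak_current / (0.4463 * n * Fc * concentration *
                    sqrt(n * Fc * scan_rate * diffusion_coefficient /
                           (Rc * temperature)))
}

#' Convert potentials between SCE and SHE reference scales
#'
#' Applies the fixed saturated-calomel offset `SHE = SCE + 0.2412 V` (25 C
#' tabulated value; in a non-isothermal cell the reference is thermostatted,
#' so the offset is treated as temperature-independent).
#'
#' @param E Potential(s), V.
#' @param from,to Reference electrode names, `"SCE"` or `"SHE"`.
#' @param temperature Unused placeholder for future temperature-dependent
#'   offsets; kept so call sites can state the cell temperature.
#' @return Converted potential(s), V.
#' @examples
#' convert_reference(0, from = "SCE", to = "SHE") # +0.2412
#' @export
convert_reference <- function(E, from = c("SCE", "SHE"),
                              to = c("SHE", "SCE"), temperature = 298.15) {
  from <- match.arg(from); to <- match.arg(to)
  offset <- 0.2412
  to_she <- c(SCE = offset, SHE = 0)
  E + to_she[[from]] - to_she[[to]]
}
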