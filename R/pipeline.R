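#' End-to-end pipeline helpers
#'
#' Thin orchestration over the simulation, processing, thermodynamics,
#' titration and kinetics stages, for driving whole analyses from a few
#' calls: each helper takes files or tidy tables, runs the corresponding
#' stage, and returns tibbles (plus fitted objects where relevant).
#'
#' @name pfv_pipeline
NULL

#' @describeIn pfv_pipeline Simulate a batch of CVs and write them (plus a
#'   JSON ground-truth manifest) to `dir`. `configs` is a list of
#'   [cv_config()]s. Returns a tibble of file paths.
#' @param configs List of [cv_config()] objects.
#' @param dir Output directory (created if needed).
#' @export
pfv_simulate <- function(configs, dir) {
  if (inherits(configs, "cv_config")) configs <- list(configs)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(seq_along(configs), function(i) {
    vg <- simulate_surface_cv(configs[[i]])
    path <- file.path(dir, sprintf("cv_%03d.csv", i))
    write_voltammogram(vg, path)
    tibble::tibble(file = path,
                   scan_rate_V_per_s = configs[[i]]$scan_rate,
                   temperature_K = configs[[i]]$temperature)
  })
  manifest <- lapply(configs, function(cf) unclass(cv_ground_truth(cf)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rows
}

#' @describeIn pfv_pipeline Read voltammogram files, pick peaks, and (when
#'   the electrode area is recorded) compute surface coverage. Returns one
#'   row per file.
#' @param files Character vector of voltammogram file paths.
#' @export
pfv_process <- function(files) {
  purrr::map_dfr(files, function(p) {
    vg <- read_voltammogram(p)
    pk <- find_peaks(vg)
    row <- dplyr::bind_cols(tibble::tibble(file = p), tibble::as_tibble(pk))
    row$temperature_K <- attr(vg, "temperature")
    row$scan_rate_V_per_s <- attr(vg, "scan_rate")
    if (is.finite(attr(vg, "electrode_area"))) {
      row$gamma0_mol_cm2 <- surface_coverage(pk, vg)$gamma0_mol_cm2
    }
    row
  })
}

#' @describeIn pfv_pipeline Reduction thermodynamics for one or several
#'   conditions. `data` has columns `temperature_K`, `E_V` and optionally
#'   `condition_label`; returns a list with the per-condition `thermo`
#'   table (one [thermo_summary()] row each) and, when four or more
#'   conditions are present, the [compensation_regression()].
#' @param data Tidy table (see details of each stage).
#' @param n Number of electrons.
#' @param T_ref Reference temperature, K.
#' @export
pfv_thermo <- function(data, n = 1L, T_ref = 298.15) {
  if (!"condition_label" %in% names(data)) data$condition_label <- "all"
  groups <- split(tibble::as_tibble(data), data$condition_label)
  fits <- purrr::map(groups, function(g) {
    thermo_summary(g, n = n, T_ref = T_ref,
                   condition_label = g$condition_label[1])
  })
  tab <- purrr::map_dfr(fits, glance)
  comp <- if (length(fits) >= 4) compensation_regression(fits) else NULL
  list(thermo = tab, fits = fits, compensation = comp)
}

#' @describeIn pfv_pipeline Fit the pH titration model to a table with
#'   columns `pH`, `E_V`; passes `...` to [fit_ph_model()].
#' @param ... Passed through to the underlying fitter.
#' @export
pfv_pka <- function(data, ...) {
  fit_ph_model(data, ...)
}

#' @describeIn pfv_pipeline Full ET-kinetics chain: Laviron ks per
#'   temperature, Arrhenius activation enthalpy, Marcus reorganization
#'   energy, and the tunneling-distance interval. `trumpets` is a list of
#'   trumpet tables (each carrying its temperature). Returns a list with
#'   the per-temperature `ks` table, the `arrhenius` fit, `lambda_kJ_mol`,
#'   and the `tunneling` interval (evaluated at `distance_temperature`).
#' @param trumpets List of `trumpet_data` tables at different temperatures.
#' @param distance_temperature Temperature (K) at which the tunneling
#'   distance is evaluated; defaults to the median trumpet temperature.
#' @export
pfv_kinetics <- function(trumpets, distance_temperature = NULL, ...) {
  if (inherits(trumpets, "trumpet_data")) trumpets <- list(trumpets)
  ks_tab <- purrr::map_dfr(trumpets, function(tr) {
    glance(extract_ks(tr, ...))
  })
  out <- list(ks = ks_tab, arrhenius = NULL, lambda_kJ_mol = NA_real_,
              tunneling = NULL)
  usable <- ks_tab[!ks_tab$lower_bound & is.finite(ks_tab$ks_s1), ]
  if (nrow(usable) >= 3 &&
      diff(range(usable$temperature_K)) >= 15) {
    arr <- arrhenius_activation(
      tibble::tibble(temperature_K = usable$temperature_K, ks = usable$ks_s1)
    )
    out$arrhenius <- arr
    out$lambda_kJ_mol <- marcus_lambda(max(0, arr$activation_enthalpy))
    Td <- distance_temperature %||% stats::median(usable$temperature_K)
    i_ref <- which.min(abs(usable$temperature_K - Td))
    out$tunneling <- tunneling_distance_interval(
      ks = usable$ks_s1[i_ref],
      activation_enthalpy = max(0, arr$activation_enthalpy),
      temperature = usable$temperature_K[i_ref]
    )
  }
  out
}
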