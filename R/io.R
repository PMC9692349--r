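#' Read and write voltammogram files
#'
#' The package's voltammogram file dialect is plain UTF-8 CSV: `# key: value`
#' header lines, then a column header `potential_V,current_A`, then
#' point-decimal numeric rows. Mandatory header keys are `scan_rate_V_per_s`
#' and `temperature_K` (or `temperature_C`); recognised optional keys are
#' `electrode_area_cm2`, `n_electrons`, `reference`, `pH`, `sam_label` and
#' `segment_split_index` (number of rows in the first sweep segment).
#' Unknown keys are preserved verbatim in the metadata. Simulation ground
#' truth round-trips through `gt_*` header keys.
#'
#' `write_voltammogram()` followed by `read_voltammogram()` is the identity
#' on values (numeric round-trip to at least 12 significant digits) and on
#' metadata.
#'
#' @param path File path.
#' @param vg A `voltammogram`.
#' @return `read_voltammogram()` returns a `voltammogram`;
#'   `write_voltammogram()` returns `path` invisibly.
#' @name voltammogram_io
NULL

.known_keys <- c("scan_rate_V_per_s", "temperature_K", "temperature_C",
                 "electrode_area_cm2", "n_electrons", "segment_split_index")

#' @rdname voltammogram_io
#' @export
write_voltammogram <- function(vg, path) {
  stopifnot(inherits(vg, "voltammogram"))
  num <- function(x) formatC(x, digits = 15, format = "g")
  hdr <- c(
    paste0("# scan_rate_V_per_s: ", num(attr(vg, "scan_rate"))),
    paste0("# temperature_K: ", num(attr(vg, "temperature")))
  )
  if (is.finite(attr(vg, "electrode_area"))) {
    hdr <- c(hdr, paste0("# electrode_area_cm2: ",
                         num(attr(vg, "electrode_area"))))
  }
  hdr <- c(hdr, paste0("# n_electrons: ", attr(vg, "n_electrons")))
  if ("segment" %in% names(vg) && any(vg$segment == 1L)) {
    hdr <- c(hdr, paste0("# segment_split_index: ", sum(vg$segment == 1L)))
  }
  md <- attr(vg, "metadata")
  for (k in names(md)) {
    v <- md[[k]]
    hdr <- c(hdr, paste0("# ", k, ": ",
                         if (is.numeric(v)) num(v) else as.character(v)))
  }
  gt <- attr(vg, "ground_truth")
  if (!is.null(gt)) {
    for (k in names(gt)) {
      v <- gt[[k]]
      if (is.null(v)) next
      hdr <- c(hdr, paste0("# gt_", k, ": ",
                           if (is.numeric(v)) num(v)
                           else as.character(v)))
    }
  }
  rows <- paste(num(vg$potential_V), num(vg$current_A), sep = ",")
  writeLines(c(hdr, "potential_V,current_A", rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname voltammogram_io
#' @export
read_voltammogram <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  is_hdr <- startsWith(lines, "#")
  hdr <- sub("^#\\s*", "", lines[is_hdr])
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  .assert(length(body) >= 1 && identical(trimws(body[1]), "potential_V,current_A"),
          "format error: missing `potential_V,current_A` column header",
          class = "pfv_format_error")
  body <- body[-1]
  .assert(length(body) >= 2,
          "format error: fewer than 2 data rows", class = "pfv_format_error")

  # split on the FIRST colon only: values may themselves contain colons
  keys <- sub(":.*$", "", hdr)
  vals <- sub("^[^:]*:", "", hdr)
  header <- stats::setNames(as.list(trimws(vals)), trimws(keys))

  n_commas <- lengths(regmatches(body, gregexpr(",", body, fixed = TRUE)))
  if (any(n_commas != 1L)) {
    rlang::abort(paste0(
      "format error: expected exactly one comma per data row ",
      "(point-decimal numbers only; comma decimal separators are not ",
      "accepted), offending row ", which(n_commas != 1L)[1]
    ), class = "pfv_format_error")
  }
  parts <- strsplit(body, ",", fixed = TRUE)
  pot <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  cur <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(pot) || anyNA(cur)) {
    rlang::abort(paste0("format error: non-numeric value in data row ",
                        which(is.na(pot) | is.na(cur))[1]),
                 class = "pfv_format_error")
  }

  for (k in "scan_rate_V_per_s") {
    .assert(k %in% names(header),
            paste0("format error: missing mandatory header key `", k, "`"),
            class = "pfv_format_error")
  }
  .assert(any(c("temperature_K", "temperature_C") %in% names(header)),
          "format error: missing mandatory header key `temperature_K`",
          class = "pfv_format_error")
  scan_rate <- as.numeric(header$scan_rate_V_per_s)
  temperature <- if (!is.null(header$temperature_K)) {
    as.numeric(header$temperature_K)
  } else {
    as.numeric(header$temperature_C) + 273.15
  }
  area <- if (!is.null(header$electrode_area_cm2)) {
    as.numeric(header$electrode_area_cm2)
  } else NA_real_
  n_el <- if (!is.null(header$n_electrons)) {
    as.integer(header$n_electrons)
  } else 1L

  n <- length(pot)
  split_idx <- if (!is.null(header$segment_split_index)) {
    as.integer(header$segment_split_index)
  } else {
    .detect_split(pot)
  }
  segment <- rep(2L, n)
  if (!is.na(split_idx) && split_idx >= 1L) {
    segment[seq_len(min(split_idx, n))] <- 1L
  } else {
    segment[] <- 1L
  }
  for (s in unique(segment)) {
    dp <- diff(pot[segment == s])
    .assert(all(dp > 0) || all(dp < 0),
            paste0("segmentation error: segment ", s,
                   " is not monotone in potential"),
            class = "pfv_segmentation_error")
  }
  time_s <- c(0, cumsum(abs(diff(pot)) / scan_rate))

  gt_keys <- startsWith(names(header), "gt_")
  gt <- NULL
  if (any(gt_keys)) {
    gt <- lapply(header[gt_keys], function(v) {
      nv <- suppressWarnings(as.numeric(v))
      if (is.na(nv)) {
        if (v %in% c("TRUE", "FALSE")) as.logical(v) else v
      } else nv
    })
    names(gt) <- sub("^gt_", "", names(header)[gt_keys])
    class(gt) <- "cv_ground_truth"
  }
  md <- header[!gt_keys & !(names(header) %in% .known_keys)]

  new_voltammogram(
    tibble::tibble(segment = segment, time_s = time_s,
                   potential_V = pot, current_A = cur),
    scan_rate = scan_rate, temperature = temperature,
    electrode_area = area, n_electrons = n_el,
    metadata = md, ground_truth = gt
  )
}

# Index of the last row of the forward sweep, from the turning point of the
# potential program; NA when the sweep never reverses.
.detect_split <- function(pot) {
  d <- diff(pot)
  turn <- which(d[-1] * d[-length(d)] < 0)
  if (length(turn) == 0) NA_integer_ else turn[1] + 1L
}
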