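# Print-run tables: the bench-side record of a printing experiment.
# File schema (one row per condition):
#   gauge, speed_m_s, pressure_1e5Pa, width_um, width_sd_um, status
# status is one of: continuous, discontinuous, not_printed.
# Width columns are empty exactly when status == not_printed.

.print_run_statuses <- c("continuous", "discontinuous", "not_printed")

#' Read and write print-run tables
#'
#' A print run records one printing condition -- nozzle gauge, stage speed
#' (m/s), gauge pressure (in units of 1e5 Pa, the bench convention) -- plus
#' the measured line width (mean and sd, micrometres) and a continuity
#' status: `continuous` (a uniform strand), `discontinuous` (a strand was
#' printed but broke into defects/droplets), or `not_printed` (pressure too
#' low to dispense at that speed; no width exists). Continuity is a
#' data-provided label, never predicted by the model.
#'
#' `read_print_runs()` validates the table, resolves gauges through the
#' nozzle registry, and converts to SI: columns `diameter`, `length` (m),
#' `pressure` (Pa), `speed` (m/s) are added alongside the measured widths
#' in micrometres. An `over_extrusion` flag (measured width strictly larger
#' than the nozzle inner diameter) is computed for measured rows.
#'
#' @param path File path (CSV; `#` comment lines ignored).
#' @param registry Nozzle registry tibble, see [default_nozzles()].
#' @return A tibble of class `print_runs`.
#' @examples
#' runs <- read_print_runs(strandwidth_example("table2_line_widths.csv"))
#' dplyr::count(runs, status)
#' @export
read_print_runs <- function(path, registry = default_nozzles()) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  raw <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      gauge = readr::col_character(),
      speed_m_s = readr::col_double(),
      pressure_1e5Pa = readr::col_double(),
      width_um = readr::col_double(),
      width_sd_um = readr::col_double(),
      status = readr::col_character()
    )
  )
  need <- c("gauge", "speed_m_s", "pressure_1e5Pa", "width_um", "width_sd_um", "status")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    stop_validation(sprintf("print-run table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn(sprintf("print-run table %s is empty.", path))
    out <- as_tibble(raw[, need])
    class(out) <- c("print_runs", class(out))
    return(out)
  }
  problems <- character(0)
  row_ids <- seq_len(nrow(raw))
  bad_status <- !(raw$status %in% .print_run_statuses)
  if (any(bad_status)) {
    problems <- c(problems, sprintf(
      "row %d: unknown status '%s'", row_ids[bad_status], raw$status[bad_status]
    ))
  }
  i <- match(raw$gauge, registry$gauge)
  if (anyNA(i)) {
    problems <- c(problems, sprintf(
      "row %d: unknown gauge '%s'", row_ids[is.na(i)], raw$gauge[is.na(i)]
    ))
  }
  nonpos <- function(x) !is.na(x) & x <= 0
  for (col in c("speed_m_s", "pressure_1e5Pa", "width_um")) {
    bad <- nonpos(raw[[col]])
    if (any(bad)) {
      problems <- c(problems, sprintf("row %d: non-positive %s", row_ids[bad], col))
    }
  }
  bad_sd <- !is.na(raw$width_sd_um) & raw$width_sd_um < 0
  if (any(bad_sd)) {
    problems <- c(problems, sprintf("row %d: negative width_sd_um", row_ids[bad_sd]))
  }
  measured <- raw$status %in% c("continuous", "discontinuous")
  bad_na <- (measured & is.na(raw$width_um)) | (!measured & !is.na(raw$width_um) & !bad_status)
  if (any(bad_na, na.rm = TRUE)) {
    problems <- c(problems, sprintf(
      "row %d: width must be present iff status != not_printed", row_ids[which(bad_na)]
    ))
  }
  if (length(problems) > 0) {
    stop_validation(paste(
      c("invalid print-run table:", problems), collapse = "\n  "
    ))
  }
  out <- tibble(
    gauge = raw$gauge,
    diameter = registry$diameter[i],
    length = registry$length[i],
    pressure = raw$pressure_1e5Pa * 1e5,
    speed = raw$speed_m_s,
    width_um = raw$width_um,
    width_sd_um = raw$width_sd_um,
    status = raw$status,
    over_extrusion = ifelse(
      is.na(raw$width_um), NA, um_to_m(raw$width_um) > registry$diameter[i]
    )
  )
  class(out) <- c("print_runs", class(out))
  out
}

#' @rdname read_print_runs
#' @param x A `print_runs` tibble (or a data frame with its columns).
#' @export
write_print_runs <- function(x, path) {
  need <- c("gauge", "speed", "pressure", "width_um", "width_sd_um", "status")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop_validation(sprintf("print runs are missing column(s): %s", paste(miss, collapse = ", ")))
  }
  out <- tibble(
    gauge = x$gauge,
    speed_m_s = x$speed,
    pressure_1e5Pa = x$pressure / 1e5,
    width_um = x$width_um,
    width_sd_um = x$width_sd_um,
    status = x$status
  )
  readr::write_csv(out, path, progress = FALSE, na = "")
  invisible(path)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return A file path (or a character vector of file names).
#' @examples
#' strandwidth_example()
#' @export
strandwidth_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "strandwidth")))
  }
  path <- system.file("extdata", file, package = "strandwidth")
  if (path == "") stop_validation(sprintf("no packaged file '%s'.", file))
  path
}

#' The published pluronic line-width measurements
#'
#' The packaged 27-condition factorial print-run table for 24.5 wt %
#' pluronic F127: 3 nozzles (21G/25G/27G) x 3 speeds (0.01/0.02/0.03 m/s)
#' x 3 gauge pressures (1/2/3 x 1e5 Pa), with measured line widths
#' (mean +/- sd, micrometres) and continuity status. 8 conditions produced
#' no extrudate (`not_printed`), 11 produced a discontinuous strand, and 8
#' a continuous one.
#'
#' @inheritParams read_print_runs
#' @return A `print_runs` tibble with 27 rows; see [read_print_runs()].
#' @examples
#' table2_print_runs()
#' @export
table2_print_runs <- function(registry = default_nozzles()) {
  read_print_runs(strandwidth_example("table2_line_widths.csv"), registry)
}

#' Classify over-extrusion
#'
#' A strand is over-extruded when its width strictly exceeds the nozzle
#' inner diameter (a width exactly equal to the bore is not flagged).
#'
#' @param width_um Measured (or predicted) strand width, micrometres.
#' @param nozzle A [nozzle_spec()], or a gauge label resolved through
#'   `registry`.
#' @param registry Nozzle registry, see [default_nozzles()].
#' @return Logical vector.
#' @examples
#' classify_over_extrusion(c(3215.85, 325.48, 514), nozzle("21G"))
#' @export
classify_over_extrusion <- function(width_um, nozzle, registry = default_nozzles()) {
  check_positive(width_um, "width_um")
  if (is.character(nozzle)) nozzle <- nozzle(nozzle, registry)
  stopifnot(inherits(nozzle, "nozzle_spec"))
  um_to_m(width_um) > nozzle$diameter
}

#' Compare model predictions with measured print runs
#'
#' For every measured run (status `continuous` or, by default, also
#' `discontinuous`; `not_printed` rows are always excluded) the width
#' model is evaluated at the run's condition and compared with the
#' measurement. Relative error is `(predicted - measured) / measured`.
#' The `d2_sqrt_p` column (D^2 sqrt(dP)) is the abscissa of the classical
#' width-scaling plot on which model and experiment are usually overlaid.
#'
#' Whether discontinuous strands belong in a width comparison is
#' genuinely ambiguous -- their widths are measured, but the model assumes
#' a continuous strand -- so `include_discontinuous` is exposed as a
#' toggle (default `TRUE`, i.e. compare every measured run).
#'
#' @param runs A `print_runs` tibble, see [read_print_runs()].
#' @param ink An [ink_params()] (or [fit_power_law()] result).
#' @param include_discontinuous Keep runs whose strand broke up? Default
#'   `TRUE`.
#' @return A tibble of class `width_comparison`, one row per compared run,
#'   sorted by `d2_sqrt_p`: the run's condition, `width_um` (measured),
#'   `width_pred_um`, `relative_error`, `d2_sqrt_p`, `status`. Use
#'   [glance()] for the overall summary (RMSE in micrometres, mean
#'   absolute relative error) and [comparison_summary()] for the per-speed
#'   breakdown.
#' @examples
#' cmp <- compare_runs(table2_print_runs(), pluronic_ink("24.5"))
#' glance(cmp)
#' @export
compare_runs <- function(runs, ink, include_discontinuous = TRUE) {
  ink <- as_ink_params(ink)
  if (!is.data.frame(runs)) stop_validation("`runs` must be a print_runs tibble.")
  keep <- c("continuous", if (include_discontinuous) "discontinuous")
  meas <- filter(as_tibble(runs), .data$status %in% keep, !is.na(.data$width_um))
  if (nrow(meas) == 0) {
    stop_usage("no measured print runs to compare (all not_printed or excluded).")
  }
  out <- meas |>
    mutate(
      width_pred_um = m_to_um(capillary_width(
        ink$n, ink$eta, .data$diameter, .data$length, .data$pressure, .data$speed
      )),
      relative_error = (.data$width_pred_um - .data$width_um) / .data$width_um,
      d2_sqrt_p = .data$diameter^2 * sqrt(.data$pressure)
    ) |>
    arrange(.data$d2_sqrt_p, .data$speed)
  class(out) <- c("width_comparison", class(out))
  attr(out, "ink") <- ink
  out
}

#' @export
#' @method glance width_comparison
glance.width_comparison <- function(x, ...) {
  tibble(
    n_runs = nrow(x),
    rmse_um = sqrt(mean((x$width_pred_um - x$width_um)^2)),
    mean_abs_rel_error = mean(abs(x$relative_error)),
    median_abs_rel_error = stats::median(abs(x$relative_error))
  )
}

#' Per-speed summary of a width comparison
#'
#' @param x A [compare_runs()] result.
#' @return A tibble with one row per stage speed plus an `overall` row:
#'   number of runs, RMSE (um), mean absolute relative error.
#' @export
comparison_summary <- function(x) {
  stopifnot(inherits(x, "width_comparison"))
  per <- x |>
    group_by(.data$speed) |>
    summarise(
      n_runs = dplyr::n(),
      rmse_um = sqrt(mean((.data$width_pred_um - .data$width_um)^2)),
      mean_abs_rel_error = mean(abs(.data$relative_error)),
      .groups = "drop"
    ) |>
    mutate(group = sprintf("speed %g m/s", .data$speed)) |>
    select("group", "n_runs", "rmse_um", "mean_abs_rel_error")
  overall <- glance(x) |>
    mutate(group = "overall") |>
    select("group", "n_runs", "rmse_um", "mean_abs_rel_error")
  bind_rows(per, overall)
}

#' Write a width comparison as CSV or JSON
#'
#' @param x A [compare_runs()] result.
#' @param path Output path; format chosen by extension (`.json` for JSON,
#'   anything else CSV).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  stopifnot(inherits(x, "width_comparison"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(rows = as_tibble(x), summary = comparison_summary(x)),
      path, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    readr::write_csv(as_tibble(x), path, progress = FALSE, na = "")
  }
  invisible(path)
}
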