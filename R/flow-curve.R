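#' Flow curve: paired shear rate / apparent viscosity measurements
#'
#' A flow curve is the standard steady-shear rheometer export: apparent
#' viscosity (Pa.s) measured over a ramp of shear rates (1/s), as produced
#' by a cone-plate instrument. `flow_curve()` validates and canonically
#' sorts the measurements; duplicated shear rates are allowed and treated
#' as replicate points downstream.
#'
#' @param shear_rate Numeric vector of shear rates, 1/s, strictly positive.
#' @param viscosity Numeric vector of apparent viscosities, Pa.s, strictly
#'   positive, same length as `shear_rate`.
#' @param label Free-text description (ink name, concentration, ...).
#' @return A tibble of class `flow_curve` with columns `shear_rate` and
#'   `viscosity`, sorted by shear rate, carrying `label` as an attribute.
#' @examples
#' flow_curve(c(1, 10, 100), 1.04 * c(1, 10, 100)^(0.0511 - 1))
#' @export
flow_curve <- function(shear_rate, viscosity, label = NULL) {
  if (length(shear_rate) != length(viscosity)) {
    stop_validation("shear_rate and viscosity must have the same length.")
  }
  if (length(shear_rate) < 2) {
    stop_validation("a flow curve needs at least 2 measurements.")
  }
  check_positive(shear_rate, "shear_rate")
  check_positive(viscosity, "viscosity")
  ord <- order(shear_rate)
  out <- tibble(shear_rate = shear_rate[ord], viscosity = viscosity[ord])
  attr(out, "label") <- label
  class(out) <- c("flow_curve", class(out))
  out
}

#' @rdname flow_curve
#' @param x A data frame with columns `shear_rate` and `viscosity`.
#' @export
as_flow_curve <- function(x, label = NULL) {
  if (inherits(x, "flow_curve") && is.null(label)) return(x)
  if (!is.data.frame(x) || !all(c("shear_rate", "viscosity") %in% names(x))) {
    stop_validation("need a data frame with columns shear_rate and viscosity.")
  }
  flow_curve(x$shear_rate, x$viscosity, label = label %||% attr(x, "label"))
}

# readr-style column aliases accepted in flow-curve files
.flow_curve_aliases <- c(
  "shear_rate_1/s" = "shear_rate", "shear_rate_1_s" = "shear_rate",
  "shear_rate" = "shear_rate",
  "viscosity_Pa_s" = "viscosity", "viscosity_pa_s" = "viscosity",
  "viscosity" = "viscosity"
)

#' Read and write flow-curve files
#'
#' Delimited text with a header; comma or tab delimiter is sniffed
#' automatically and lines starting with `#` are ignored. Expected columns
#' are `shear_rate_1/s` and `viscosity_Pa_s` (bare `shear_rate` /
#' `viscosity` are also accepted).
#'
#' @param path File path.
#' @param label Optional label for the curve; defaults to the file name.
#' @return `read_flow_curve()`: a [flow_curve()].
#' @export
read_flow_curve <- function(path, label = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 50L)
  header <- header[!startsWith(trimws(header), "#") & nzchar(trimws(header))]
  if (length(header) == 0) stop_validation(sprintf("no data in %s", path))
  delim <- if (grepl("\t", header[[1]])) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, comment = "#", show_col_types = FALSE,
    trim_ws = TRUE, progress = FALSE
  )
  hits <- .flow_curve_aliases[names(.flow_curve_aliases) %in% names(raw)]
  names(raw)[match(names(hits), names(raw))] <- hits
  if (!all(c("shear_rate", "viscosity") %in% names(raw))) {
    stop_validation(sprintf(
      "%s: expected columns 'shear_rate_1/s' and 'viscosity_Pa_s' (got: %s)",
      path, paste(names(raw), collapse = ", ")
    ))
  }
  flow_curve(raw$shear_rate, raw$viscosity, label = label %||% basename(path))
}

#' @rdname read_flow_curve
#' @param x A [flow_curve()] (or data frame with its columns).
#' @export
write_flow_curve <- function(x, path) {
  x <- as_flow_curve(x)
  out <- tibble(`shear_rate_1/s` = x$shear_rate, viscosity_Pa_s = x$viscosity)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
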