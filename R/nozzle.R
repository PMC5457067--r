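#' Nozzle specification
#'
#' A dispensing nozzle is characterised by its gauge label, inner diameter
#' `D` and capillary length `L`. Both lengths are in metres internally; the
#' constructor takes the diameter in micrometres because that is how needle
#' catalogues quote it.
#'
#' @param gauge Character label, e.g. `"21G"`.
#' @param diameter_um Inner diameter in micrometres.
#' @param length_m Capillary (needle) length in metres. Default 0.005 m,
#'   the length of the blunt dispensing tips used in the printing study.
#' @return An object of class `nozzle_spec`: a list with elements `gauge`,
#'   `diameter` (m) and `length` (m).
#' @examples
#' nozzle_spec("21G", diameter_um = 514)
#' @seealso [nozzle()] for registry lookup, [default_nozzles()] for the
#'   shipped registry.
#' @export
nozzle_spec <- function(gauge, diameter_um, length_m = 0.005) {
  stopifnot(is.character(gauge), length(gauge) == 1)
  check_positive(diameter_um, "diameter_um")
  check_positive(length_m, "length_m")
  structure(
    list(gauge = gauge, diameter = um_to_m(diameter_um), length = length_m),
    class = "nozzle_spec"
  )
}

#' @export
print.nozzle_spec <- function(x, ...) {
  cat(sprintf(
    "<nozzle %s: D = %.0f um, L = %.3f m>\n",
    x$gauge, m_to_um(x$diameter), x$length
  ))
  invisible(x)
}

#' Default nozzle registry
#'
#' The gauge-to-inner-diameter map used in the printing study: 21G = 514 um,
#' 25G = 260 um, 27G = 210 um, all with a 5 mm capillary length. Gauge to ID
#' mappings vary by vendor, so every function that resolves a gauge label
#' accepts a `registry` argument with this tibble's schema.
#'
#' @return A tibble with columns `gauge`, `diameter` (m), `length` (m).
#' @examples
#' default_nozzles()
#' @export
default_nozzles <- function() {
  tibble(
    gauge = c("21G", "25G", "27G"),
    diameter = um_to_m(c(514, 260, 210)),
    length = 0.005
  )
}

#' Look up a nozzle by gauge label
#'
#' @param gauge Gauge label, e.g. `"25G"`.
#' @param registry A tibble with columns `gauge`, `diameter`, `length`;
#'   defaults to [default_nozzles()].
#' @return A [nozzle_spec()].
#' @examples
#' nozzle("25G")
#' @export
nozzle <- function(gauge, registry = default_nozzles()) {
  i <- match(gauge, registry$gauge)
  if (anyNA(i)) {
    stop_validation(sprintf(
      "unknown nozzle gauge '%s'; registry has: %s",
      paste(gauge[is.na(i)], collapse = ", "),
      paste(registry$gauge, collapse = ", ")
    ))
  }
  nozzle_spec(registry$gauge[i], m_to_um(registry$diameter[i]), registry$length[i])
}

as_nozzle_tbl <- function(nozzles, registry = default_nozzles()) {
  if (inherits(nozzles, "nozzle_spec")) {
    return(tibble(
      gauge = nozzles$gauge, diameter = nozzles$diameter, length = nozzles$length
    ))
  }
  if (is.character(nozzles)) {
    i <- match(nozzles, registry$gauge)
    if (anyNA(i)) {
      stop_validation(sprintf(
        "unknown nozzle gauge '%s'.", paste(nozzles[is.na(i)], collapse = ", ")
      ))
    }
    return(registry[i, c("gauge", "diameter", "length")])
  }
  if (is.data.frame(nozzles)) {
    need <- c("gauge", "diameter", "length")
    if (!all(need %in% names(nozzles))) {
      stop_validation("nozzle table needs columns gauge, diameter, length.")
    }
    if (nrow(nozzles) == 0) stop_usage("nozzle table is empty.")
    check_positive(nozzles$diameter, "diameter")
    check_positive(nozzles$length, "length")
    return(as_tibble(nozzles[, need]))
  }
  if (is.list(nozzles) && all(vapply(nozzles, inherits, logical(1), "nozzle_spec"))) {
    return(bind_rows(lapply(nozzles, as_nozzle_tbl)))
  }
  stop_validation("cannot interpret `nozzles`; give gauges, nozzle_spec(s) or a table.")
}
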