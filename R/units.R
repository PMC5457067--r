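# Unit boundary: the model is strictly SI internally (m, Pa, s, Pa.s);
# bench conventions (um widths, "x 10^5 Pa" pressures, cP viscosities)
# are converted here and nowhere else.

#' Unit conversions used at the I/O boundary
#'
#' The capillary-flow model works in SI units (metres, pascals, seconds).
#' Print-run tables and nozzle catalogues quote widths and diameters in
#' micrometres and viscosities are often reported in centipoise; these
#' helpers convert at the boundary.
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @examples
#' pas_to_cp(1.04)  # 1040 cP
#' um_to_m(514)     # 5.14e-4 m
#' @name units
NULL

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
m_to_um <- function(x) x * 1e6

#' @rdname units
#' @export
pas_to_cp <- function(x) x * 1000

#' @rdname units
#' @export
cp_to_pas <- function(x) x / 1000

#' Parse a gauge pressure to pascals
#'
#' Accepts plain numbers (taken as Pa), scientific notation strings
#' (`"1e5"`), and suffixed forms: `"1bar"`, `"250kPa"`, `"0.1MPa"`,
#' `"100000Pa"`. 1 bar = 1e5 Pa. Whitespace between number and suffix is
#' allowed; matching is case-insensitive for the SI prefixes except that
#' `Pa`/`kPa`/`MPa`/`bar` are recognised as written here.
#'
#' @param x Numeric or character vector of pressures.
#' @return Numeric vector of gauge pressures in Pa.
#' @examples
#' parse_pressure(c("1e5", "100000", "1bar", "250 kPa"))
#' @export
parse_pressure <- function(x) {
  if (is.numeric(x)) {
    check_positive(x, "pressure")
    return(as.numeric(x))
  }
  if (!is.character(x)) stop_validation("pressure must be numeric or character.")
  one <- function(s) {
    s <- gsub("\\s+", "", s)
    m <- regmatches(s, regexec("^([0-9.eE+-]+)(bar|MPa|kPa|Pa)?$", s))[[1]]
    if (length(m) == 0 || m[2] == "" || is.na(suppressWarnings(as.numeric(m[2])))) {
      stop_validation(sprintf("cannot parse pressure '%s'.", s))
    }
    val <- as.numeric(m[2])
    mult <- switch(ifelse(m[3] == "", "Pa", m[3]),
      Pa = 1, kPa = 1e3, MPa = 1e6, bar = 1e5
    )
    val * mult
  }
  out <- vapply(x, one, numeric(1), USE.NAMES = FALSE)
  check_positive(out, "pressure")
  out
}
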