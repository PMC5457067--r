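#' Ink (bioink) rheology constants
#'
#' The width prediction consumes two material constants: the power-law index
#' `n` (dimensionless; n < 1 means shear-thinning) and the apparent
#' viscosity `eta` in Pa.s, defined at the reference shear rate of 1 1/s.
#' Under that reference the apparent viscosity is numerically the power-law
#' consistency coefficient (Pa.s^n).
#'
#' @param n Power-law index, > 0.
#' @param eta Apparent viscosity at 1 1/s, in Pa.s, > 0.
#' @param label Free-text ink description.
#' @return An object of class `ink_params`.
#' @examples
#' ink_params(n = 0.0511, eta = 1.04, label = "pluronic F127 24.5 wt %")
#' @export
ink_params <- function(n, eta, label = "ink") {
  check_positive(n, "n")
  check_positive(eta, "eta")
  stopifnot(length(n) == 1, length(eta) == 1)
  structure(list(n = n, eta = eta, label = label), class = "ink_params")
}

#' @export
print.ink_params <- function(x, ...) {
  cat(sprintf(
    "<ink '%s': n = %.4g, eta = %.4g Pa.s (%.4g cP) at 1 1/s>\n",
    x$label, x$n, x$eta, pas_to_cp(x$eta)
  ))
  invisible(x)
}

#' Published pluronic F127 ink constants
#'
#' Rheology constants of the two pluronic F127 hydrogel concentrations used
#' in the printing study: 24.5 wt % (n = 0.0511, eta = 1.04 Pa.s) and
#' 30 wt % (n = 0.1656, eta = 1.46 Pa.s), both dispensed through 5 mm
#' needles.
#'
#' @return `pluronic_inks()`: a tibble with columns `label`, `n`, `eta`,
#'   `needle_length`. `pluronic_ink()`: a single [ink_params()].
#' @examples
#' pluronic_inks()
#' pluronic_ink("24.5 wt %")
#' @export
pluronic_inks <- function() {
  tibble(
    label = c("pluronic F127 24.5 wt %", "pluronic F127 30 wt %"),
    concentration = c("24.5 wt %", "30 wt %"),
    n = c(0.0511, 0.1656),
    eta = c(1.04, 1.46),
    needle_length = 0.005
  )
}

#' @rdname pluronic_inks
#' @param concentration `"24.5 wt %"` or `"30 wt %"` (a unique prefix such
#'   as `"24.5"` or `"30"` also works).
#' @export
pluronic_ink <- function(concentration = "24.5 wt %") {
  tab <- pluronic_inks()
  i <- pmatch(concentration, tab$concentration)
  if (is.na(i)) {
    stop_validation(sprintf(
      "unknown pluronic concentration '%s'; available: %s",
      concentration, paste(tab$concentration, collapse = ", ")
    ))
  }
  ink_params(n = tab$n[i], eta = tab$eta[i], label = tab$label[i])
}

#' Convert a fitted power-law model to prediction constants
#'
#' @param x A [fit_power_law()] result.
#' @param label Optional label override.
#' @return An [ink_params()] whose `eta` is the fitted viscosity at the
#'   reference shear rate (1 1/s).
#' @export
as_ink_params <- function(x, label = NULL) {
  UseMethod("as_ink_params")
}

#' @export
as_ink_params.ink_params <- function(x, label = NULL) {
  if (!is.null(label)) x$label <- label
  x
}

#' @export
as_ink_params.power_law_fit <- function(x, label = NULL) {
  ink_params(n = x$n, eta = x$eta0, label = label %||% x$label %||% "fitted ink")
}
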