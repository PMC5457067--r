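#' Fit the power-law (Ostwald-de Waele) viscosity model
#'
#' The power-law model writes apparent viscosity as
#' `eta = eta0 * shear_rate^(n - 1)` with the reference shear rate fixed at
#' 1 1/s, so `eta0` is the viscosity at 1 1/s (numerically the consistency
#' coefficient, Pa.s^n). Taking logs gives a straight line,
#' `log eta = (n - 1) log shear_rate + log eta0`, which is fitted by
#' unweighted ordinary least squares in log10 space: the slope is `n - 1`
#' and the back-transformed intercept is `eta0`.
#'
#' Shear-thinning inks have n < 1 (viscosity falls with shear rate); n = 1
#' is Newtonian. The fit window restricts which shear rates enter the
#' regression; rheometer flow curves are usually only power-law over a
#' limited range, and the printing study fitted from the start of the ramp
#' up to 1500 1/s, so `window = c(min(data$shear_rate), 1500)` reproduces
#' that choice.
#'
#' @param data A [flow_curve()] or data frame with columns `shear_rate`
#'   (1/s) and `viscosity` (Pa.s).
#' @param window Optional length-2 numeric `c(min, max)` shear-rate
#'   interval (inclusive); default uses the full curve.
#' @return An object of class `power_law_fit` with elements `n`, `eta0`,
#'   `reference_shear_rate` (1), `r_squared`, `window`, `n_points`,
#'   standard errors `n_se`/`log10_eta0_se`, the in-window `data`, and the
#'   curve `label`. Methods: [tidy()], [glance()], [predict()],
#'   [autoplot()], [write_fit_report()].
#' @examples
#' g <- c(1, 10, 100, 1000)
#' fit <- fit_power_law(flow_curve(g, 1.04 * g^(0.0511 - 1)))
#' glance(fit)
#' @export
fit_power_law <- function(data, window = NULL) {
  curve <- as_flow_curve(data)
  if (is.null(window)) {
    window <- range(curve$shear_rate)
  } else {
    if (length(window) != 2 || !is.numeric(window) || anyNA(window) ||
      window[1] <= 0 || window[1] >= window[2]) {
      stop_validation("window must be numeric c(min, max) with 0 < min < max.")
    }
  }
  used <- curve[curve$shear_rate >= window[1] & curve$shear_rate <= window[2], ]
  if (nrow(used) < 2 || length(unique(used$shear_rate)) < 2) {
    stop_degenerate(sprintf(
      "power-law fit needs >= 2 distinct in-window shear rates (have %d point(s) in [%g, %g]).",
      nrow(used), window[1], window[2]
    ))
  }
  lx <- log10(used$shear_rate)
  ly <- log10(used$viscosity)
  fit <- stats::lm(ly ~ lx)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ly - mean(ly))^2)
  # constant-viscosity input has tss == 0: a flat line fits it perfectly
  r2 <- if (tss <= .Machine$double.eps * max(1, sum(ly^2))) {
    if (rss <= 1e-20) 1 else 0
  } else {
    max(0, min(1, 1 - rss / tss))
  }
  # summary.lm warns on numerically perfect fits; noiseless curves are a
  # legitimate input here, so silence it and keep the (near-zero) SEs
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
    error = function(e) c(NA_real_, NA_real_)
  )
  n <- slope + 1
  if (n <= 0) {
    stop_domain(sprintf(
      "fitted power-law index n = %.4g is not positive; the curve thins faster than any power-law fluid this model supports.", n
    ))
  }
  structure(
    list(
      n = n,
      eta0 = 10^intercept,
      reference_shear_rate = 1,
      r_squared = r2,
      window = as.numeric(window),
      n_points = nrow(used),
      n_se = unname(se[2]),
      log10_eta0_se = unname(se[1]),
      data = used,
      label = attr(curve, "label")
    ),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "<power-law fit%s: n = %.4g, eta0 = %.4g Pa.s at 1 1/s, R^2 = %.4f, %d points in [%g, %g] 1/s>\n",
    if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
    x$n, x$eta0, x$r_squared, x$n_points, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Apparent viscosity of a power-law fluid
#'
#' Evaluates `eta0 * shear_rate^(n - 1)`. At the reference shear rate of
#' 1 1/s this returns `eta0` exactly; for a Newtonian fluid (n = 1) it is
#' shear-independent.
#'
#' @param object A `power_law_fit` or [ink_params()] (whose `eta` plays the
#'   role of `eta0` at the 1 1/s reference).
#' @param shear_rate Positive numeric vector, 1/s.
#' @return Apparent viscosity in Pa.s, vectorised over `shear_rate`.
#' @examples
#' apparent_viscosity(ink_params(n = 0.5, eta = 4), shear_rate = 4)  # 2
#' @export
apparent_viscosity <- function(object, shear_rate) {
  check_positive(shear_rate, "shear_rate")
  par <- if (inherits(object, "power_law_fit")) {
    list(n = object$n, eta0 = object$eta0)
  } else if (inherits(object, "ink_params")) {
    list(n = object$n, eta0 = object$eta)
  } else {
    stop_validation("`object` must be a power_law_fit or ink_params.")
  }
  par$eta0 * shear_rate^(par$n - 1)
}

#' @export
predict.power_law_fit <- function(object, shear_rate, ...) {
  apparent_viscosity(object, shear_rate)
}

#' @export
#' @method tidy power_law_fit
tidy.power_law_fit <- function(x, ...) {
  tibble(
    term = c("n", "eta0"),
    estimate = c(x$n, x$eta0),
    # eta0 = 10^b, so SE(eta0) ~ ln(10) * eta0 * SE(b) (delta method)
    std.error = c(x$n_se, log(10) * x$eta0 * x$log10_eta0_se)
  )
}

#' @export
#' @method glance power_law_fit
glance.power_law_fit <- function(x, ...) {
  tibble(
    n = x$n,
    eta0 = x$eta0,
    reference_shear_rate = x$reference_shear_rate,
    r_squared = x$r_squared,
    n_points = x$n_points,
    window_min = x$window[1],
    window_max = x$window[2]
  )
}

#' Write a power-law fit report as JSON
#'
#' @param fit A `power_law_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "power_law_fit"))
  jsonlite::write_json(
    list(
      n = fit$n, eta0 = fit$eta0,
      reference_shear_rate = fit$reference_shear_rate,
      r_squared = fit$r_squared,
      window = fit$window, n_points = fit$n_points
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
#' @method autoplot power_law_fit
autoplot.power_law_fit <- function(object, ...) {
  dat <- object$data
  line <- tibble(
    shear_rate = exp(seq(log(min(dat$shear_rate)), log(max(dat$shear_rate)),
      length.out = 100
    ))
  )
  line$viscosity <- apparent_viscosity(object, line$shear_rate)
  ggplot2::ggplot(dat, ggplot2::aes(.data$shear_rate, .data$viscosity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = line, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "shear rate (1/s)", y = "apparent viscosity (Pa.s)",
      title = object$label,
      subtitle = sprintf(
        "n = %.4g, eta0 = %.4g Pa.s, R² = %.4f",
        object$n, object$eta0, object$r_squared
      )
    )
}
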