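# Seeded synthetic-data generators. Both emulate what the lab instruments
# would produce -- a cone-plate flow curve and a factorial print-run table --
# from known ground truth, so every pipeline stage is testable end to end.
# Noise is multiplicative lognormal: viscosities and widths are strictly
# positive and their scatter scales roughly with the mean.

#' Simulate a rheometer flow curve with known ground truth
#'
#' Generates `eta_i = true_eta0 * g_i^(true_n - 1) * exp(e_i)` with
#' `e_i ~ Normal(0, noise_sigma^2)` over a log-spaced shear-rate grid.
#' Defaults reproduce the 24.5 wt % pluronic rheology (n = 0.0511,
#' eta0 = 1.04 Pa.s) over 0.1 to 1500 1/s, the range a cone-plate ramp of
#' a printable hydrogel typically covers.
#'
#' @param true_n Ground-truth power-law index.
#' @param true_eta0 Ground-truth viscosity at 1 1/s, Pa.s.
#' @param n_points Number of grid points.
#' @param shear_rate_range `c(min, max)` of the log-spaced grid, 1/s.
#' @param noise_sigma Lognormal noise scale (sd of log viscosity); 0 gives
#'   the exact power-law curve.
#' @param seed Integer seed; the generator uses a private RNG stream and
#'   the same (arguments, seed) pair is bit-reproducible. `NULL` draws
#'   from the session RNG.
#' @param label Curve label.
#' @return A [flow_curve()] carrying `true_n`, `true_eta0` and `seed` as
#'   attributes.
#' @examples
#' fc <- simulate_flow_curve(noise_sigma = 0.05, seed = 1)
#' glance(fit_power_law(fc))
#' @export
simulate_flow_curve <- function(true_n = 0.0511, true_eta0 = 1.04,
                                n_points = 50,
                                shear_rate_range = c(0.1, 1500),
                                noise_sigma = 0.05, seed = NULL,
                                label = "synthetic flow curve") {
  check_positive(true_n, "true_n")
  check_positive(true_eta0, "true_eta0")
  if (n_points < 2) stop_validation("n_points must be >= 2.")
  check_positive(shear_rate_range, "shear_rate_range")
  if (shear_rate_range[1] >= shear_rate_range[2]) {
    stop_validation("shear_rate_range must be increasing.")
  }
  if (noise_sigma < 0) stop_validation("noise_sigma must be >= 0.")
  g <- exp(seq(log(shear_rate_range[1]), log(shear_rate_range[2]),
    length.out = n_points
  ))
  eps <- with_local_seed(seed, stats::rnorm(n_points, 0, noise_sigma))
  eta <- true_eta0 * g^(true_n - 1) * exp(eps)
  out <- flow_curve(g, eta, label = label)
  attr(out, "true_n") <- true_n
  attr(out, "true_eta0") <- true_eta0
  attr(out, "seed") <- seed
  out
}

#' Simulate a factorial print-run table from the width model
#'
#' Evaluates the width model over a [design_grid()] and perturbs each
#' predicted width with multiplicative lognormal noise,
#' `measured = predicted * exp(e)`, `e ~ Normal(0, width_noise_sigma^2)`.
#' All runs are labelled `continuous` (the generator emulates the regime
#' the model describes; dropout and strand breakup are not simulated).
#' Defaults reproduce the published factorial design: 3 nozzles x 3
#' pressures (1-3 x 1e5 Pa) x 3 speeds (0.01-0.03 m/s) = 27 runs.
#'
#' @param ink An [ink_params()].
#' @inheritParams design_grid
#' @param width_noise_sigma Lognormal noise scale on widths; 0 gives
#'   exactly the model widths.
#' @param seed Integer seed (private RNG stream, reproducible); `NULL`
#'   draws from the session RNG.
#' @return A `print_runs` tibble (schema of [read_print_runs()]) with the
#'   generating `ink`, `width_noise_sigma`, `seed` and the noiseless
#'   `width_true_um` carried as attributes/column.
#' @examples
#' runs <- simulate_print_runs(pluronic_ink("24.5"), seed = 1)
#' compare_runs(runs, pluronic_ink("24.5")) |> glance()
#' @export
simulate_print_runs <- function(ink,
                                nozzles = default_nozzles(),
                                pressures = c(1e5, 2e5, 3e5),
                                speeds = c(0.01, 0.02, 0.03),
                                width_noise_sigma = 0.05, seed = NULL,
                                registry = default_nozzles()) {
  ink <- as_ink_params(ink)
  if (width_noise_sigma < 0) stop_validation("width_noise_sigma must be >= 0.")
  pred <- sweep_design(ink, nozzles, pressures, speeds, registry)
  eps <- with_local_seed(seed, stats::rnorm(nrow(pred), 0, width_noise_sigma))
  out <- pred |>
    mutate(
      width_true_um = .data$width_pred_um,
      width_um = .data$width_pred_um * exp(eps),
      width_sd_um = 0,
      status = "continuous",
      over_extrusion = um_to_m(.data$width_um) > .data$diameter
    ) |>
    select(
      "gauge", "diameter", "length", "pressure", "speed",
      "width_um", "width_sd_um", "status", "over_extrusion", "width_true_um"
    )
  class(out) <- c("print_runs", class(out))
  attr(out, "ink") <- ink
  attr(out, "width_noise_sigma") <- width_noise_sigma
  attr(out, "seed") <- seed
  out
}
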