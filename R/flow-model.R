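# Capillary-flow chain for a power-law fluid in a cylindrical nozzle.
# All equation-layer functions are vectorised over their numeric arguments
# and work strictly in SI units (m, Pa, s, Pa.s).

#' Capillary-flow equation layer
#'
#' The elementary relations of pressure-driven capillary flow that the
#' width prediction chains together:
#'
#' * `wall_shear_stress()`: fully developed laminar flow supports a wall
#'   shear stress `tau_w = D * dP / (4 L)` regardless of rheology.
#' * `wall_shear_rate()`: the true wall shear rate of a power-law fluid,
#'   `gamma_w = ((3n + 1) / 4n) * 32 Q / (pi D^3)`, i.e. the Newtonian
#'   value times the Rabinowitsch correction `(3n + 1) / 4n`.
#' * `strand_flow_rate()`: volume conservation between the nozzle and a
#'   deposited strand of constant circular cross-section `d` moving with
#'   the stage at speed `v`: `Q = pi d^2 v / 4`.
#'
#' @param diameter Nozzle inner diameter D, m.
#' @param pressure Gauge pressure dP, Pa (assumed to act entirely across
#'   the nozzle; entrance/exit losses neglected).
#' @param length Nozzle capillary length L, m.
#' @param n Power-law index (> 0).
#' @param flow_rate Volumetric flow rate Q, m^3/s.
#' @param width Strand diameter d, m.
#' @param speed Stage speed v, m/s.
#' @return Numeric vector: Pa, 1/s, or m^3/s respectively.
#' @examples
#' wall_shear_stress(diameter = 514e-6, pressure = 1e5, length = 0.005)  # 2570 Pa
#' @name capillary_flow
NULL

#' @rdname capillary_flow
#' @export
wall_shear_stress <- function(diameter, pressure, length) {
  check_positive(diameter, "diameter")
  check_positive(pressure, "pressure")
  check_positive(length, "length")
  diameter * pressure / (4 * length)
}

#' @rdname capillary_flow
#' @export
wall_shear_rate <- function(n, flow_rate, diameter) {
  check_positive(n, "n")
  check_positive(flow_rate, "flow_rate")
  check_positive(diameter, "diameter")
  warn_tiny_n(n)
  ((3 * n + 1) / (4 * n)) * 32 * flow_rate / (pi * diameter^3)
}

#' @rdname capillary_flow
#' @export
strand_flow_rate <- function(width, speed) {
  check_positive(width, "width")
  check_positive(speed, "speed")
  pi * width^2 * speed / 4
}

# (3n+1)/4n blows up as n -> 0; allow but flag, since rheometer fits of
# strongly shear-thinning gels can land here and amplify noise.
warn_tiny_n <- function(n) {
  if (any(n < 1e-4)) {
    warn("power-law index n < 1e-4: the Rabinowitsch factor (3n+1)/4n is very large and results are sensitive to noise in n.")
  }
  invisible(n)
}

#' Closed-form width prediction and its inverses (equation layer)
#'
#' Combining wall shear stress, the Rabinowitsch-corrected wall shear rate
#' evaluated at the deposited-strand flow rate, and the constitutive law
#' `tau_w = eta * gamma_w` gives the printed line width
#'
#'   `d = D^2 * sqrt( dP * (4n / (3n + 1)) / (32 eta L v) )`
#'
#' `capillary_pressure()` and `capillary_speed()` are its exact algebraic
#' inverses: the gauge pressure (or stage speed) that yields a target
#' width with the other parameters held fixed. At n = 1 the prediction
#' reduces to the Newtonian Hagen-Poiseuille form
#' `d^2 = dP * D^4 / (32 eta L v)`.
#'
#' The apparent viscosity `eta` enters as a constant (its value at the
#' 1 1/s reference shear rate); it is not re-evaluated at the wall shear
#' rate.
#'
#' @inheritParams capillary_flow
#' @param eta Apparent viscosity, Pa.s.
#' @return Numeric vector: width (m), pressure (Pa) or speed (m/s).
#' @examples
#' capillary_width(
#'   n = 0.0511, eta = 1.04, diameter = 514e-6, length = 0.005,
#'   pressure = 1e5, speed = 0.01
#' ) # ~8.62e-4 m
#' @name capillary_design
NULL

#' @rdname capillary_design
#' @export
capillary_width <- function(n, eta, diameter, length, pressure, speed) {
  check_positive(n, "n"); check_positive(eta, "eta")
  check_positive(diameter, "diameter"); check_positive(length, "length")
  check_positive(pressure, "pressure"); check_positive(speed, "speed")
  warn_tiny_n(n)
  diameter^2 * sqrt(pressure * (4 * n / (3 * n + 1)) / (32 * eta * length * speed))
}

#' @rdname capillary_design
#' @export
capillary_pressure <- function(n, eta, diameter, length, width, speed) {
  check_positive(n, "n"); check_positive(eta, "eta")
  check_positive(diameter, "diameter"); check_positive(length, "length")
  check_positive(width, "width"); check_positive(speed, "speed")
  warn_tiny_n(n)
  32 * eta * length * ((3 * n + 1) / (4 * n)) * (width^2 / diameter^4) * speed
}

#' @rdname capillary_design
#' @export
capillary_speed <- function(n, eta, diameter, length, width, pressure) {
  check_positive(n, "n"); check_positive(eta, "eta")
  check_positive(diameter, "diameter"); check_positive(length, "length")
  check_positive(width, "width"); check_positive(pressure, "pressure")
  warn_tiny_n(n)
  (diameter^4 / (32 * eta * length * width^2)) * (4 * n / (3 * n + 1)) * pressure
}

#' Enumerate a factorial print design
#'
#' Builds the Cartesian product of nozzles, gauge pressures and stage
#' speeds as a tidy table of print conditions, in deterministic
#' (nozzle, speed, pressure) order. The printing study used 3 nozzles x
#' 3 pressures x 3 speeds = 27 conditions.
#'
#' @param nozzles Gauge labels (resolved via `registry`), a
#'   [nozzle_spec()], a list of them, or a tibble with columns `gauge`,
#'   `diameter`, `length`.
#' @param pressures Gauge pressures; numeric Pa or strings accepted by
#'   [parse_pressure()].
#' @param speeds Stage speeds, m/s.
#' @param registry Nozzle registry, see [default_nozzles()].
#' @return A tibble with one row per condition: `gauge`, `diameter` (m),
#'   `length` (m), `pressure` (Pa), `speed` (m/s).
#' @examples
#' design_grid(c("21G", "25G", "27G"), c(1e5, 2e5, 3e5), c(0.01, 0.02, 0.03))
#' @export
design_grid <- function(nozzles = default_nozzles(),
                        pressures = c(1e5, 2e5, 3e5),
                        speeds = c(0.01, 0.02, 0.03),
                        registry = default_nozzles()) {
  noz <- as_nozzle_tbl(nozzles, registry)
  if (length(pressures) == 0 || length(speeds) == 0 || nrow(noz) == 0) {
    stop_usage("nozzles, pressures and speeds must all be non-empty.")
  }
  pressures <- parse_pressure(pressures)
  check_positive(speeds, "speeds")
  grid <- tidyr::crossing(
    noz_i = seq_len(nrow(noz)), speed = sort(speeds), pressure = sort(pressures)
  )
  out <- tibble(
    gauge = noz$gauge[grid$noz_i],
    diameter = noz$diameter[grid$noz_i],
    length = noz$length[grid$noz_i],
    pressure = grid$pressure,
    speed = grid$speed
  )
  out
}

#' Predict printed line width over a table of conditions
#'
#' The data-frame verb around [capillary_width()]: for each row of print
#' conditions it reports the predicted strand width together with the rest
#' of the capillary-flow chain evaluated there, and flags over-extrusion
#' (predicted width strictly larger than the nozzle inner diameter).
#'
#' @param data A tibble of conditions with columns `diameter` (m),
#'   `length` (m), `pressure` (Pa), `speed` (m/s) -- e.g. from
#'   [design_grid()] -- or with a `gauge` column resolvable through
#'   `registry`.
#' @param ink An [ink_params()] (or a [fit_power_law()] result).
#' @param registry Nozzle registry used when only `gauge` is present.
#' @return The input tibble with columns added: `width_pred` (m),
#'   `width_pred_um`, `tau_w` (Pa), `gamma_w` (1/s), `flow_rate` (m^3/s),
#'   `d2_sqrt_p` (the scaling abscissa D^2 * sqrt(dP), m^2 Pa^0.5) and
#'   `over_extrusion` (logical).
#' @examples
#' design_grid("21G", 1e5, 0.01) |> predict_width(pluronic_ink("24.5"))
#' @export
predict_width <- function(data, ink, registry = default_nozzles()) {
  ink <- as_ink_params(ink)
  data <- resolve_conditions(data, registry)
  out <- mutate(as_tibble(data),
    width_pred = capillary_width(
      ink$n, ink$eta, .data$diameter, .data$length, .data$pressure, .data$speed
    ),
    width_pred_um = m_to_um(.data$width_pred),
    tau_w = wall_shear_stress(.data$diameter, .data$pressure, .data$length),
    flow_rate = strand_flow_rate(.data$width_pred, .data$speed),
    gamma_w = wall_shear_rate(ink$n, .data$flow_rate, .data$diameter),
    d2_sqrt_p = .data$diameter^2 * sqrt(.data$pressure),
    over_extrusion = .data$width_pred > .data$diameter
  )
  attr(out, "ink") <- ink
  out
}

#' Required pressure / speed for a target width (data-frame verbs)
#'
#' Inverse process design over a table: given a target strand width and
#' one of the two kinematic knobs, solve the width model for the other.
#' `required_pressure()` needs columns `target_width` (m) and `speed`
#' (m/s) and adds `pressure_req` (Pa); `required_speed()` needs
#' `target_width` and `pressure` (Pa) and adds `speed_req` (m/s).
#'
#' @inheritParams predict_width
#' @return The input tibble with the solved column appended.
#' @examples
#' tibble::tibble(gauge = "21G", target_width = 862.22e-6, speed = 0.01) |>
#'   required_pressure(pluronic_ink("24.5"))
#' @export
required_pressure <- function(data, ink, registry = default_nozzles()) {
  ink <- as_ink_params(ink)
  data <- resolve_conditions(data, registry, need = c("target_width", "speed"))
  mutate(as_tibble(data),
    pressure_req = capillary_pressure(
      ink$n, ink$eta, .data$diameter, .data$length, .data$target_width, .data$speed
    )
  )
}

#' @rdname required_pressure
#' @export
required_speed <- function(data, ink, registry = default_nozzles()) {
  ink <- as_ink_params(ink)
  data <- resolve_conditions(data, registry, need = c("target_width", "pressure"))
  mutate(as_tibble(data),
    speed_req = capillary_speed(
      ink$n, ink$eta, .data$diameter, .data$length, .data$target_width, .data$pressure
    )
  )
}

#' Sweep an ink over a factorial design
#'
#' Convenience composition of [design_grid()] and [predict_width()]:
#' enumerates the (nozzle, speed, pressure) grid and evaluates the full
#' prediction report on every condition, ordered by (nozzle, speed,
#' pressure). The `d2_sqrt_p` column is the abscissa of the classical
#' width-scaling plot (d against D^2 sqrt(dP)).
#'
#' @inheritParams design_grid
#' @param ink An [ink_params()].
#' @return A prediction tibble, see [predict_width()].
#' @examples
#' sweep_design(pluronic_ink("24.5")) # 27 rows
#' @export
sweep_design <- function(ink,
                         nozzles = default_nozzles(),
                         pressures = c(1e5, 2e5, 3e5),
                         speeds = c(0.01, 0.02, 0.03),
                         registry = default_nozzles()) {
  design_grid(nozzles, pressures, speeds, registry) |>
    predict_width(ink, registry)
}

# Ensure a conditions table carries diameter/length (resolving gauge via
# the registry when needed) plus whatever numeric columns the verb needs.
resolve_conditions <- function(data, registry, need = c("pressure", "speed")) {
  if (!is.data.frame(data)) stop_validation("`data` must be a data frame of print conditions.")
  data <- as_tibble(data)
  if (!all(c("diameter", "length") %in% names(data))) {
    if (!"gauge" %in% names(data)) {
      stop_validation("conditions need either diameter+length columns or a gauge column.")
    }
    i <- match(data$gauge, registry$gauge)
    if (anyNA(i)) {
      stop_validation(sprintf(
        "unknown nozzle gauge '%s'.", paste(unique(data$gauge[is.na(i)]), collapse = ", ")
      ))
    }
    if (!"diameter" %in% names(data)) data$diameter <- registry$diameter[i]
    if (!"length" %in% names(data)) data$length <- registry$length[i]
  }
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop_validation(sprintf("conditions are missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (nrow(data) == 0) stop_usage("conditions table is empty.")
  for (col in unique(c("diameter", "length", need))) check_positive(data[[col]], col)
  data
}
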