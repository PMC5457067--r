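# Capillary-flow chain: equation layer, forward prediction, inverses,
# factorial sweeps.

test_that("wall shear stress is D*dP/(4L)", {
  expect_equal(wall_shear_stress(514e-6, 1e5, 0.005), 2570)
  expect_equal(wall_shear_stress(0.02, 7, 0.005), 7) # D = 4L: prefactor 1
  cond <- random_conditions(50, seed = 11)
  expect_equal(
    wall_shear_stress(cond$diameter, 2 * cond$pressure, cond$length),
    2 * wall_shear_stress(cond$diameter, cond$pressure, cond$length),
    tolerance = 1e-15
  )
})

test_that("wall shear rate carries the Rabinowitsch correction", {
  expect_equal(wall_shear_rate(1, pi / 32, 1), 1)
  # hand-evaluated 32Q/(pi D^3) for a 514 um bore
  D <- 514e-6
  Q <- pi * 1e-10
  newtonian <- 32 * Q / (pi * D^3) # = 32e-10 / D^3
  expect_equal(wall_shear_rate(1, Q, D), newtonian, tolerance = 1e-12)
  expect_equal(wall_shear_rate(0.5, Q, D), (2.5 / 2) * newtonian, tolerance = 1e-12)
  # (3n+1)/4n decreases in n
  ns <- c(0.05, 0.1, 0.5, 1, 2, 10)
  rates <- wall_shear_rate(ns, Q, D)
  expect_true(all(diff(rates) < 0))
  expect_error(wall_shear_rate(-1, Q, D), class = "strandwidth_domain_error")
  expect_warning(wall_shear_rate(5e-5, Q, D), "Rabinowitsch")
})

test_that("strand flow rate is pi d^2 v / 4 and composes into the kinematic shear rate", {
  expect_equal(strand_flow_rate(2e-4, 0.01), pi * 1e-10)
  expect_equal(strand_flow_rate(2 / sqrt(pi), 1), 1)
  cond <- random_conditions(200, seed = 12)
  d <- withr::with_seed(13, runif(200, 50e-6, 2000e-6))
  expect_equal(
    wall_shear_rate(cond$n, strand_flow_rate(d, cond$speed), cond$diameter),
    oracle_gamma_w(cond$n, d, cond$speed, cond$diameter),
    tolerance = 1e-12
  )
})

test_that("forward width prediction matches the hand-derived closed form", {
  # frozen worked example: 24.5 wt % ink, 21G nozzle, 1e5 Pa, 0.01 m/s
  d <- capillary_width(0.0511, 1.04, 514e-6, 0.005, 1e5, 0.01)
  expect_equal(d, 8.622216e-4, tolerance = 1e-6)
  expect_equal(d, oracle_width(0.0511, 1.04, 514e-6, 0.005, 1e5, 0.01), tolerance = 1e-15)
  # d scales as 1/sqrt(v): tripling the speed divides d by sqrt(3)
  d3 <- capillary_width(0.0511, 1.04, 514e-6, 0.005, 1e5, 0.03)
  expect_equal(d / d3, sqrt(3), tolerance = 1e-12)
  # Newtonian unit case
  expect_equal(capillary_width(1, 1, 1, 1, 32, 1), 1, tolerance = 1e-15)
})

test_that("predict_width reports the full chain consistently", {
  ink <- table1_ink()
  rep <- design_grid("21G", 1e5, 0.01) |> predict_width(ink)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$width_pred_um, 862.2216, tolerance = 1e-6)
  expect_equal(rep$tau_w, 2570)
  expect_equal(rep$flow_rate, strand_flow_rate(rep$width_pred, 0.01))
  expect_equal(rep$gamma_w, oracle_gamma_w(ink$n, rep$width_pred, 0.01, 514e-6))
  expect_true(rep$over_extrusion) # 862 um > 514 um bore
  expect_equal(rep$d2_sqrt_p, (514e-6)^2 * sqrt(1e5))
  # the constitutive law closes the chain: tau_w = eta * gamma_w at d*
  expect_equal(rep$tau_w, ink$eta * rep$gamma_w, tolerance = 1e-12)
})

test_that("scaling laws hold to 1e-12 relative error on randomized inputs", {
  cond <- random_conditions(1000, seed = 21)
  k <- withr::with_seed(22, runif(1000, 0.2, 5))
  base <- with(cond, capillary_width(n, eta, diameter, length, pressure, speed))
  up_p <- with(cond, capillary_width(n, eta, diameter, length, k^2 * pressure, speed))
  dn_v <- with(cond, capillary_width(n, eta, diameter, length, pressure, speed / k^2))
  up_d <- with(cond, capillary_width(n, eta, k * diameter, length, pressure, speed))
  expect_lt(max(rel_err(up_p / base, k)), 1e-12)
  expect_lt(max(rel_err(dn_v / base, k)), 1e-12)
  expect_lt(max(rel_err(up_d / base, k^2)), 1e-12)
})

test_that("pressure and speed inverses round-trip the forward model", {
  cond <- random_conditions(1000, seed = 31)
  d <- with(cond, capillary_width(n, eta, diameter, length, pressure, speed))
  p_back <- with(cond, capillary_pressure(n, eta, diameter, length, d, speed))
  v_back <- with(cond, capillary_speed(n, eta, diameter, length, d, pressure))
  expect_lt(max(rel_err(p_back, cond$pressure)), 1e-9)
  expect_lt(max(rel_err(v_back, cond$speed)), 1e-9)
  # Newtonian unit cases
  expect_equal(capillary_pressure(1, 1, 1, 1, 1, 1), 32)
  expect_equal(capillary_speed(1, 1, 1, 1, 1, 32), 1)
  # worked-example inverse: target 862.23 um back to ~1e5 Pa
  p <- capillary_pressure(0.0511, 1.04, 514e-6, 0.005, 862.23e-6, 0.01)
  expect_equal(p, 1e5, tolerance = 1e-4)
  # halving the target width quadruples the required speed
  v1 <- capillary_speed(0.3, 2, 300e-6, 0.005, 400e-6, 2e5)
  v2 <- capillary_speed(0.3, 2, 300e-6, 0.005, 200e-6, 2e5)
  expect_equal(v2 / v1, 4, tolerance = 1e-12)
})

test_that("data-frame inverse verbs solve for the missing knob", {
  ink <- table1_ink()
  tab <- tibble::tibble(gauge = "21G", target_width = 862.2216e-6, speed = 0.01) |>
    required_pressure(ink)
  expect_equal(tab$pressure_req, 1e5, tolerance = 1e-6)
  tab2 <- tibble::tibble(gauge = "21G", target_width = 862.2216e-6, pressure = 1e5) |>
    required_speed(ink)
  expect_equal(tab2$speed_req, 0.01, tolerance = 1e-6)
  expect_error(
    required_pressure(tibble::tibble(gauge = "21G", speed = 0.01), ink),
    class = "strandwidth_validation_error"
  )
})

test_that("Newtonian limit matches the Hagen-Poiseuille oracle", {
  cond <- random_conditions(200, seed = 41)
  got <- with(cond, capillary_width(1, eta, diameter, length, pressure, speed))
  ref <- with(cond, oracle_width_newtonian(eta, diameter, length, pressure, speed))
  expect_lt(max(rel_err(got, ref)), 1e-12)
})

test_that("design grids enumerate the factorial Cartesian product", {
  full <- design_grid(c("21G", "25G", "27G"), c(1e5, 2e5, 3e5), c(0.01, 0.02, 0.03))
  expect_equal(nrow(full), 27)
  expect_equal(nrow(dplyr::distinct(full)), 27)
  expect_equal(nrow(design_grid("21G", 1e5, 0.01)), 1)
  expect_equal(nrow(design_grid(c("21G", "25G"), c(1e5, 2e5, 3e5), 0.01)), 6)
  # deterministic (nozzle, speed, pressure) ordering
  expect_equal(full$gauge, rep(c("21G", "25G", "27G"), each = 9))
  expect_equal(full$speed[1:9], rep(c(0.01, 0.02, 0.03), each = 3))
  expect_equal(full$pressure[1:3], c(1e5, 2e5, 3e5))
  expect_error(design_grid(character(0), 1e5, 0.01), class = "strandwidth_usage_error")
  expect_error(design_grid("21G", numeric(0), 0.01), class = "strandwidth_usage_error")
  expect_error(design_grid("19G", 1e5, 0.01), class = "strandwidth_validation_error")
})

test_that("sweeps are monotone in pressure and depend on (D, dP) only through D^2 sqrt(dP)", {
  ink <- table1_ink()
  sw <- sweep_design(ink)
  expect_equal(nrow(sw), 27)
  by_noz_speed <- dplyr::group_by(sw, gauge, speed)
  incr <- dplyr::summarise(
    by_noz_speed,
    ok = all(diff(width_pred_um[order(pressure)]) > 0), .groups = "drop"
  )
  expect_true(all(incr$ok))
  # trade D for dP keeping D^2 sqrt(dP) fixed: same width at fixed speed
  a <- design_grid(tibble::tibble(gauge = "a", diameter = 400e-6, length = 0.005),
    pressures = 1.6e5, speeds = 0.02
  ) |> predict_width(ink)
  k <- 1.25
  b <- design_grid(
    tibble::tibble(gauge = "b", diameter = 400e-6 * k, length = 0.005),
    pressures = 1.6e5 / k^4, speeds = 0.02
  ) |> predict_width(ink)
  expect_equal(a$d2_sqrt_p, b$d2_sqrt_p, tolerance = 1e-12)
  expect_equal(a$width_pred, b$width_pred, tolerance = 1e-12)
})

test_that("model outputs are positive, finite and continuous on a dense grid", {
  ink <- table1_ink()
  grid <- tidyr::crossing(
    pressure = seq(1e5, 5e5, length.out = 25),
    speed = seq(0.005, 0.05, length.out = 25)
  )
  w <- capillary_width(ink$n, ink$eta, 260e-6, 0.005, grid$pressure, grid$speed)
  expect_true(all(is.finite(w)) && all(w > 0))
  # continuity: neighbouring pressures at fixed speed move the width only a little
  m <- matrix(w, nrow = 25, byrow = TRUE)
  expect_lt(max(abs(diff(m)) / m[-1, ]), 0.12)
})

test_that("non-positive physical inputs raise domain errors", {
  expect_error(capillary_width(0.5, 1, -1, 0.005, 1e5, 0.01), class = "strandwidth_domain_error")
  expect_error(capillary_width(0.5, 0, 1e-4, 0.005, 1e5, 0.01), class = "strandwidth_domain_error")
  expect_error(capillary_pressure(0.5, 1, 1e-4, 0.005, 0, 0.01), class = "strandwidth_domain_error")
  expect_error(capillary_speed(0.5, 1, 1e-4, 0.005, 1e-4, -2), class = "strandwidth_domain_error")
  expect_error(wall_shear_stress(1e-4, 1e5, 0), class = "strandwidth_domain_error")
  expect_error(strand_flow_rate(0, 0.01), class = "strandwidth_domain_error")
})
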