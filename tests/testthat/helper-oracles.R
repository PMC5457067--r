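# Independent one-line oracles, kept deliberately separate from the package
# implementation so the tests check the library against hand-derived forms.

# forward width: d = D^2 * sqrt(dP * (4n/(3n+1)) / (32 eta L v))
oracle_width <- function(n, eta, D, L, dP, v) {
  D^2 * sqrt(dP * (4 * n / (3 * n + 1)) / (32 * eta * L * v))
}

# Newtonian Hagen-Poiseuille limit: d^2 = dP * D^4 / (32 eta L v)
oracle_width_newtonian <- function(eta, D, L, dP, v) {
  sqrt(dP * D^4 / (32 * eta * L * v))
}

# wall shear rate from strand kinematics: ((3n+1)/4n) * 8 d^2 v / D^3
oracle_gamma_w <- function(n, d, v, D) {
  ((3 * n + 1) / (4 * n)) * 8 * d^2 * v / D^3
}

# draw m random positive printing conditions on realistic scales
random_conditions <- function(m, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      n = runif(m, 0.05, 1.5),
      eta = 10^runif(m, -1, 2),
      diameter = runif(m, 100e-6, 1000e-6),
      length = runif(m, 0.002, 0.02),
      pressure = 10^runif(m, 4, 6),
      speed = runif(m, 0.005, 0.05)
    )
  })
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)

table1_ink <- function() ink_params(n = 0.0511, eta = 1.04, label = "24.5 wt %")
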