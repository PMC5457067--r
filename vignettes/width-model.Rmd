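---
title: "The capillary-flow width model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The capillary-flow width model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strandwidth)
```

## The problem

A pneumatic extrusion bioprinter pushes a hydrogel through a needle with
gas pressure while the stage moves; what lands on the substrate is a
strand whose width is the print's resolution. Three process knobs control
it — nozzle bore $D$, gauge pressure $\Delta P$, stage speed $\dot v$ —
plus the ink's rheology. `strandwidth` implements an analytical model of
that width, its inverses for process design, and the comparison machinery
to confront it with bench measurements.

## Rheology: the power-law fit

Printable hydrogels such as pluronic F127 are strongly shear-thinning.
The package models them as power-law (Ostwald–de Waele) fluids,

$$\eta(\dot\gamma) = \eta_0\,\dot\gamma^{\,n-1},$$

with the reference shear rate fixed at $\dot\gamma_0 = 1\ \mathrm{s^{-1}}$,
so $\eta_0$ is "the viscosity at 1 s⁻¹" and is numerically the
consistency coefficient in Pa·sⁿ. `fit_power_law()` estimates $(n,
\eta_0)$ by unweighted ordinary least squares on
$\log_{10}\eta = (n-1)\log_{10}\dot\gamma + \log_{10}\eta_0$ — the
simplest faithful reading of the log-linear form; the base cancels in the
slope and the intercept is back-transformed. On a noiseless power-law
curve the fit is exact (checked to 1e-9 relative error in the tests) and
$R^2 = 1$.

Choices worth recording:

* **Fit window.** Real flow curves are power-law only over a limited
  range, so the window is a user-facing argument. The default is the full
  curve; `window = c(min(shear_rate), 1500)` reproduces the published
  pluronic fitting range (start of ramp to 1500 s⁻¹). Points outside the
  window never enter the regression — `n_points` in the fit object makes
  this auditable.
* **Duplicate shear rates** are kept as replicate observations in the
  regression rather than averaged; OLS weights them naturally.
* **Degenerate inputs.** Fewer than two distinct in-window shear rates is
  a degenerate-fit error (its own condition class). A constant-viscosity
  curve has zero total sum of squares; the package defines $R^2 = 1$
  there when the residuals are also zero (a flat line fits a flat curve
  perfectly) instead of propagating 0/0.
* A fitted $n \le 0$ aborts: every downstream formula divides by $4n$ and
  multiplies by $3n + 1$. Very small positive $n$ (< 1e-4) is allowed but
  warns, because the Rabinowitsch factor $(3n+1)/4n$ then amplifies any
  noise in $n$.

## The width model

Treating the nozzle as a capillary of length $L$ in steady, laminar,
incompressible, no-slip flow with entrance and exit losses neglected:

$$\tau_w = \frac{D\,\Delta P}{4L}, \qquad
  \dot\gamma_w = \frac{3n+1}{4n}\cdot\frac{32\dot Q}{\pi D^3}, \qquad
  \dot Q = \frac{\pi d^2}{4}\,\dot v,$$

the last being volume conservation into a strand of constant circular
cross-section $d$ carried away at the stage speed. Closing the chain with
the constitutive law $\tau_w = \eta\,\dot\gamma_w$ and solving for $d$:

$$d = D^2\sqrt{\frac{\Delta P}{32\,\eta L \dot v}\cdot\frac{4n}{3n+1}}.$$

`capillary_width()` implements this; `capillary_pressure()` and
`capillary_speed()` are its exact rearrangements, and the data-frame
verbs `predict_width()`, `required_pressure()`, `required_speed()` wrap
them for tables of conditions. Scaling consequences — $d \propto
\sqrt{\Delta P}$, $d \propto 1/\sqrt{\dot v}$, $d \propto D^2$, hence the
classical $d$ vs $D^2\sqrt{\Delta P}$ plot that `autoplot()` draws — are
asserted as properties in the test suite at 1e-12 relative error on 1,000
randomised conditions, and the $n = 1$ case is checked against an
independently coded Hagen–Poiseuille oracle.

**η is a constant here.** The prediction substitutes the apparent
viscosity at the 1 s⁻¹ reference as a constant; it is *not* re-evaluated
at the wall shear rate. That matches how the published constants are
used, keeps the model closed-form, and is the main physical
simplification: at wall shear rates of order 10³ s⁻¹ a shear-thinning
ink's local viscosity is far below η(1 s⁻¹). A self-consistent
variable-viscosity solution would be an iteration, and is deliberately
out of scope. Also outside the model: die swell, surface-tension breakup
into droplets, thermal sol–gel transition, gravity/spreading after
deposition — the predicted $d$ is the as-extruded diameter assumed equal
to the printed line width.

**Units.** Everything internal is SI (m, Pa, s). The boundary accepts the
bench conventions — µm widths and bores, pressures written as `"1e5"`,
`"2.5 bar"` or `"250kPa"` (`parse_pressure()`), viscosities quoted in cP
(`pas_to_cp()`) — and converts exactly once, at the edge.

## The experiment module

`read_print_runs()` ingests print-run tables (gauge, speed in m/s,
pressure in units of 10⁵ Pa, width mean ± sd in µm, continuity status)
with per-row validation; the packaged `table2_print_runs()` carries the
published 27-condition factorial for 24.5 wt % pluronic: 8 conditions
yielded no extrudate, 11 a discontinuous strand, 8 a continuous one.
Continuity is a data label, never predicted — the model has no breakup
physics. Over-extrusion is a strict inequality (width > bore; exactly
equal is not flagged).

`compare_runs()` evaluates the model at each measured run and reports
per-run relative error, plus RMSE in µm and mean absolute relative error
overall and per speed. Two metric choices: relative error is
$(\text{pred}-\text{meas})/\text{meas}$ (signed, so over- and
under-prediction are distinguishable), and RMSE is kept on the µm scale
so it is directly comparable to strand widths. Whether *discontinuous*
strands belong in the comparison is genuinely ambiguous — their widths
were measured, but the model assumes a continuous strand. The package
includes them by default (`include_discontinuous = TRUE`, covering all 19
measured runs) because dropping them silently would discard most of the
data; the toggle makes the stricter 8-run continuous-only comparison one
argument away.

## Synthetic data

Both generators draw multiplicative lognormal noise: viscosities and
widths are strictly positive, and in the measurement table the scatter
grows roughly with the mean, which lognormal noise reproduces and
additive Gaussian noise does not. Each call uses a private seeded RNG
stream (the session RNG is untouched) and records its seed.

* `simulate_flow_curve()` emulates a cone-plate ramp:
  $\eta_i = \eta_0^{*}\,\dot\gamma_i^{\,n^*-1}e^{\varepsilon_i}$,
  $\varepsilon_i \sim N(0, \sigma^2)$, on a log-spaced grid. Defaults are
  the published pluronic truth ($n^* = 0.0511$, $\eta_0^* = 1.04$ Pa·s)
  over 0.1–1500 s⁻¹ with 50 points and $\sigma = 0.05$ — a clean
  instrument day for a stable gel.
* `simulate_print_runs()` perturbs the model's own widths over the
  factorial design (default: the published 3×3×3 grid) with width noise
  $\sigma = 0.05$, all runs labelled continuous.

What passing on synthetic data shows — and does not. At zero noise the
whole pipeline (generate → fit → predict → compare) closes exactly, and
with noise the fitted $n$ is unbiased: over 200 seeds at $\sigma = 0.05$
the mean fitted $n$ sits within 2e-3 of the truth (the analytic
per-fit slope SE on that grid is ≈7e-3, so the Monte-Carlo band is a
4-sigma bound computed before freezing). This validates the algebra and
the estimation machinery. It does **not** validate the physics: the
generator is the model, so it cannot exhibit die swell, pressure-drop
transients, thixotropy, dropout at low pressure or breakup at high speed
— exactly the effects that make the packaged real measurements scatter
around the prediction with a ~46% mean relative error while still
following the $D^2\sqrt{\Delta P}$ trend.

## Problem sizes and numerics

The test suite runs the property checks on 1,000 randomised conditions
(log-uniform over realistic ranges: bores 100–1000 µm, pressures
10⁴–10⁶ Pa, speeds 5–50 mm/s, $n$ 0.05–1.5), 200 Monte-Carlo seeds for
the bias check, and 50-point synthetic curves — enough for tight
assertions while keeping the whole suite under a minute. Round-trip
identities are asserted at 1e-9 relative error and pure algebraic
identities at 1e-12; both are far above double-precision noise for these
magnitudes and were chosen from the identities' conditioning, not tuned
to observations.

## Limitations

The model is a design guide, not a metrology tool: it ranks conditions
and exposes the controlling scalings, but individual-condition errors
against real measurements are tens of percent. It has no notion of
printability limits (minimum pressure for a continuous strand, maximum
speed before defects), treats the nozzle bore as uniform, and ignores the
barrel-to-nozzle pressure drop. Extending it with a correction factor, a
variable-viscosity solution, or an empirical continuity classifier would
all fit naturally behind the current interfaces.
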