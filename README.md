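# strandwidth

Line-width (resolution) prediction for pneumatic extrusion bioprinting.

Extrusion bioprinters dispense a hydrogel "bioink" through a capillary
nozzle under gas pressure while a stage translates; the width *d* of the
deposited strand is the resolution of the print and the main knob for shape
fidelity. `strandwidth` is for people developing bioinks or tuning printers:
it answers "how wide a line will this ink print at this pressure and speed?"
and the inverse, "what pressure (or speed) do I need for a target width?"

## The model

The ink is a power-law (Ostwald–de Waele) fluid, η = η₀ γ̇ⁿ⁻¹, with the
reference shear rate γ₀ = 1 s⁻¹ so η₀ is the apparent viscosity at 1 s⁻¹.
Treating the nozzle (inner diameter *D*, length *L*) as a capillary in
steady laminar flow with no slip and negligible entrance/exit losses:

- wall shear stress: τ_w = D·ΔP / (4L)
- wall shear rate (Rabinowitsch-corrected): γ̇_w = ((3n+1)/4n) · 32Q̇/(πD³)
- volume conservation into a strand of constant circular cross-section
  moving with the stage: Q̇ = π d² v̇ / 4

Closing the chain with τ_w = η·γ̇_w gives the width prediction

    d = D² √( ΔP · (4n/(3n+1)) / (32 η L v̇) )

so d ∝ D²√ΔP and d ∝ 1/√v̇; at n = 1 it reduces to the Newtonian
Hagen–Poiseuille form d² = ΔP·D⁴/(32ηLv̇). The inverses for ΔP and v̇ are
exact algebraic rearrangements. The packaged constants are the published
pluronic F127 values (24.5 wt %: n = 0.0511, η = 1.04 Pa·s; 30 wt %:
n = 0.1656, η = 1.46 Pa·s; L = 0.005 m; 21G/25G/27G nozzles of
514/260/210 µm bore), together with the full 27-condition factorial
line-width measurement table.

## Worked example

```r
library(strandwidth)

ink <- pluronic_ink("24.5 wt %")
#> <ink 'pluronic F127 24.5 wt %': n = 0.0511, eta = 1.04 Pa.s (1040 cP) at 1 1/s>

design_grid("21G", pressures = 1e5, speeds = 0.01) |> predict_width(ink)
#>   gauge pressure speed width_pred_um tau_w  gamma_w over_extrusion
#> 1   21G    1e+05  0.01      862.2216  2570 2471.154           TRUE

compare_runs(table2_print_runs(), ink) |> glance()
#>   n_runs rmse_um mean_abs_rel_error median_abs_rel_error
#> 1     19    741.              0.457                0.523
```

Reading: through a 21G nozzle (514 µm bore) at 1×10⁵ Pa and 0.01 m/s the
model predicts a 862 µm strand — wider than the bore, so the condition is
flagged as over-extrusion; the wall of the nozzle sees 2570 Pa of shear
stress at a shear rate of ~2471 s⁻¹. Against the packaged 19 measured
print runs the model's RMSE is ~741 µm (mean absolute relative error
~46%): the measurements track the d ∝ D²√ΔP trend but individual
conditions scatter around it.

Other entry points: `fit_power_law()` fits (n, η₀) to a rheometer flow
curve (`read_flow_curve()`, `simulate_flow_curve()`);
`required_pressure()` / `required_speed()` solve the inverse design
problem; `sweep_design()` evaluates the full factorial grid;
`autoplot()` draws the standard d vs D²√ΔP picture.

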