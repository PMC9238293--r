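# pennesflow

Steady-state bio-heat modeling of thermal massage of the lumbar back, with
predicted circulation changes.

Thermal massage beds heat the lower back with a warm mat (40 °C) and four
heated rollers set between 45 and 65 °C.  Whether that helps depends on how
deep the heat reaches and how strongly local blood flow responds.
`pennesflow` models both stages:

1. **Tissue heating.** The steady Pennes bio-heat equation
   `-∇·(k∇T) + ρ_b c_b w_b (T − T_b) = Q_m`
   is solved on a voxelized layered phantom of the lumbar back (skin
   1.1 mm / subcutaneous fat 13 mm / muscle 42 mm / soft-tissue fill, with
   an optional spinal column), discretized with a 7-point finite-volume
   stencil (harmonic-mean face conductivities) and solved by deterministic
   preconditioned conjugate gradients.  The mat and the four 45 mm actuator
   discs at (±60, ±16) mm are Dirichlet patches on the skin; cut boundaries
   sit at core temperature, and uncovered skin can exchange heat
   convectively with the room.
2. **Circulation.** Local temperature elevation ΔT over the unheated
   baseline is mapped to blood flow by a calibrated sigmoid
   `F(ΔT) = F_o + (F_max − F_o) / (1 + exp(aΔT + b))`,
   fitted by least squares to five simultaneous measurements of deep leg
   temperature and femoral arterial flow (`F_o = 0.31`, `F_max = 1.22`
   L/min fixed; fitted `a ≈ −2.68`, `b ≈ 4.88`).  Flow saturates at a
   fold-change of `F_max/F_o ≈ 3.94`.

The package also ships its own verification oracles: a closed-form 1D
Pennes slab solution, a manufactured-solution convergence check, and
property tests (maximum principle, mirror symmetry, monotonicity in the
actuator setting, flow boundedness).

## Worked example

```r
library(pennesflow)

# calibrate the temperature -> flow transfer model
fit <- fit_flow_model()
fit
#> flow_model_params (logistic): F_o = 0.31, F_max = 1.22, a = -2.678, b = 4.883
#>   fitted: SSE = 0.0161 on 5 points

# solve the 45 degree C scene on the layered phantom (2 mm voxels)
vol   <- build_layered_anatomy(spacing = 2)
field <- pennes_steady(vol, actuator_layout(temperature = 45))
field
#> temperature_field: 150 x 100 x 50 voxels @ 2 mm; range 36.93-44.09 C
#>   solver: 161 iterations, relative residual 9.91e-09

# temperature under an actuator centroid at 1/2/3 cm depth
round(probe_field(field, 60, 16, c(10, 20, 30)), 2)
#> [1] 40.84 38.47 37.69

# couple to the circulation model: fold-change in blood flow at 2 cm
flow <- flow_field(field, baseline_field(vol), fit)
round(probe_field(flow, 60, 16, 20) / fit$F_o, 2)
#> [1] 1.84
```

Heat penetrates on the perfusion length scale (≈18 mm in muscle): at 45 °C
the tissue 2 cm under a roller warms by ≈1.5 °C, which the saturating flow
model already turns into a 1.8× circulation increase.  Sweeping the setting
(`run_sweep(default_config())`) shows the elevation at 2 cm growing to
≈4.8 °C at 65 °C, with the predicted flow saturated near its 3.94× ceiling
at 2 cm and reaching ≈3.2× at 3 cm — deep heating buys disproportionate
circulation because of the sigmoidal response.

The numbered scripts under `analysis/` run the full workflow and write
tables under `results/`: `01` calibrates the transfer model and compares
candidate functional forms, `02` solves the default scene and exports
fields (legacy VTK) and profiles (CSV), `03` sweeps 45–65 °C, and `04`
extracts the depth/lateral profile tables.  Configurations are declarative
(YAML; see `inst/extdata/default_config.yaml`) and validated against a
schema before any compute; identical configurations produce bit-identical
profile outputs.

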