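---
title: "Modeling deep-tissue heating and circulation changes during thermal massage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling deep-tissue heating and circulation changes during thermal massage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pennesflow)
```

## The question

Thermal massage beds heat the lower back through a warm mat (40 °C) and four
heated rollers ("actuators") whose set point ranges from 45 to 65 °C.  The
therapeutic rationale is that local heating raises blood flow, and that the
flow response is strongly nonlinear: circulation saturates once local
temperature rises a few degrees.  The quantitative questions are: how deep
does contact heating reach, and how much extra circulation does it buy at
the depths occupied by the lumbar musculature (roughly 1.5–5.5 cm)?

`pennesflow` answers both with a two-stage model: a steady-state Pennes
bio-heat solve on a voxelized phantom of the lumbar back, followed by an
empirically calibrated transfer model that maps local temperature elevation
to blood flow.

## The bio-heat model

Tissue temperature obeys the steady Pennes equation, per unit volume:

$$-\nabla\cdot(k\nabla T) + \rho_b c_b w_b\,(T - T_b) = Q_m,$$

with conductivity $k$, blood density and specific heat $\rho_b$, $c_b$,
perfusion rate $w_b$ (1/s), blood temperature $T_b$ and metabolic heat
$Q_m$.  Perfusion acts as a heat *sink* toward blood temperature.  (The
source-signed variant $+\rho_b c_b w_b (T - T_b)$, in which perfusion
amplifies any elevation, was implemented experimentally during development
and produces unphysical steady fields — interior temperatures exceeding the
hottest boundary — as well as an indefinite operator; the sink form is the
standard convention and the one consistent with the reported behavior of
heated tissue.)

The perfusion term sets a penetration length
$\lambda = \sqrt{k/(\rho_b c_b w_b)}$ — about 17.6 mm for muscle and 26 mm
for fat with the tabulated constants — which is why contact heating decays
over centimeters rather than reaching arbitrarily deep.

Temperatures are Celsius throughout; the two Kelvin-valued blood
temperatures in the property table are converted once (309.7 K → 36.55 °C,
CSF 310 K → 36.85 °C).

## The phantom

The imaging-derived geometry behind the original analysis is not publicly
available, so the computational domain is a synthetic layered phantom built
from the measured tissue thicknesses: skin 1.1 mm, subcutaneous fat 13 mm,
muscle 42 mm, with everything deeper filled by muscle-like "soft tissue".
The default box is 300 × 200 × 100 mm — large enough that the cut
boundaries sit several penetration lengths away from the heated region —
with isotropic voxels of 1 mm (production) or 2 mm (fast runs, tests).
Voxels are classified by their center against half-open layer boundaries.

An optional concentric spinal column (vertebra, epidural fat 2.2 mm, CSF
2.9 mm, cord) can be stamped into the phantom, but it is disabled by
default: the standard probe lines sit at $x = \pm 60$ mm, lateral to the
column, and the column barely perturbs them.  The vertebral shell thickness
is not reported anywhere and defaults to 10 mm, chosen so the column fits
the default domain with a plausible vertebral-body diameter; the concentric
arrangement is an acknowledged simplification.

## Boundary conditions and the actuator footprint

The posterior surface ($z = 0$) is covered by the 40 °C mat except where
the actuator discs contact the skin at their set temperature; both are
Dirichlet conditions applied at the voxel faces.  All cut boundaries are
held at core temperature (37 °C).  A convective pathway
$q_0 = h(T_{amb} - T)$ with $h = 5$ W m⁻² K⁻¹ and $T_{amb} = 25$ °C is
implemented and applies to any surface voxel left uncovered when the mat is
given a finite lateral extent; with the default full-coverage mat it is
inactive.  This resolves the tension between "external boundaries fixed to
core temperature" and the stated convective loss: convection can only act
where the skin actually faces the room.

The published actuator geometry is internally inconsistent (a two-lobed
65 mm roller cross-section versus "four actuators with a diameter of
4.5 cm" and lateral positions of ±6 cm).  We model each actuator as a
single 45 mm contact disc centered at (±60, ±16) mm.  With 45 mm discs and
32 mm vertical separation, each vertical pair overlaps into a single peanut-
shaped patch; this is intentional and mirrors the two-lobed roller.  A disc
whose *center* falls inside another disc is rejected as a placement error.

This choice has a visible consequence, discussed under *Limitations*: a
single 45 mm disc on a flat slab injects less heat than the larger merged
roller bodies pressed into a curved back, so near-actuator temperatures at
depth run below the originally reported values while midline and far-field
values agree well.

## Discretization and solver

The equation is discretized with a 7-point finite-volume stencil; the face
conductivity between dissimilar voxels is the harmonic mean of their
conductivities, the correct flux-continuous choice for layered media.
Dirichlet faces are eliminated by ghost substitution over the half-cell
distance (coefficient $2k/h^2$), keeping the operator symmetric positive
definite.  The linear system is solved by Jacobi-preconditioned conjugate
gradients from a uniform 37 °C start to a relative residual of $10^{-8}$
(configurable); the iteration is fully deterministic.  The default
300 × 200 × 100 mm domain at 1 mm spacing has six million unknowns and
solves in roughly three hundred iterations.

Verification is built into the package rather than argued:

* a closed-form 1D Pennes slab solution (`analytic_slab_1d`), matched by a
  1D-configured 3D solve (adiabatic sides) to better than 0.001 °C at
  0.5 mm spacing, far inside the 0.05 °C acceptance band;
* a manufactured-solution study (`manufactured_solution_check`) showing the
  expected second-order convergence (observed order ≈ 2.0 across 4/2/1 mm);
* property tests: the discrete maximum principle on randomized scenes,
  exact mirror symmetry for symmetric layouts, and monotonicity of the
  field in the actuator setting.

## The circulation transfer model

Blood flow is predicted from local temperature elevation
$\Delta T = T - T_{\mathrm{baseline}}$ by a sigmoid bounded between a
baseline flow $F_o$ and a maximal flow $F_{max}$:

$$F(\Delta T) = F_o + \frac{F_{max} - F_o}{1 + e^{a\Delta T + b}},
\qquad a < 0.$$

The calibration data are five simultaneous measurements of deep leg
temperature and femoral arterial flow during passive heat stress, shipped
with the package (`chiesa_flow_data()`).  Following the original
assignment, $F_o = 0.31$ L/min (the minimum measured flow) and
$F_{max} = 1.22$ L/min (the flow at the highest temperature) are fixed, and
$(a, b)$ are fitted by unweighted least squares with elevations taken
relative to 34.9 °C, the lowest measured leg temperature.  The fit is
deterministic: a fixed grid of starting points, BFGS, then a Gauss–Newton
polish that terminates on a parameter change below $10^{-10}$ (the relative
function criterion alone stalls when the residual approaches zero, e.g. on
noiseless synthetic data).  The fitted values are $a = -2.678$,
$b = 4.883$, with SSE ≈ 0.016 (L/min)².

A note on the functional form.  Written as an unbounded exponential
$F_o + (F_{max}-F_o)e^{-(a\Delta T + b)}$, the model cannot be sigmoidal,
ignores its own ceiling $F_{max}$, and at the fitted parameters predicts
physically absurd flows (tens of L/min) for elevations above ~2 °C.  The
logistic resolution above reproduces, at those same parameters, both the
calibration measurements and the published flow predictions
(1.22 / 1.11 / 0.41 / 0.33 L/min at the four depth temperatures of the
45 °C scene).  `form_resolution_oracle()` fits all three candidate forms
and tabulates the evidence.  Interestingly the clamped exponential attains
a smaller SSE on the five points than the logistic, but only the logistic
reproduces the published parameter values and downstream predictions, so it
is the default; the other forms remain selectable.

Two different baselines are used deliberately: the *calibration* measures
elevation against 34.9 °C (the unheated leg), while *predictions* on the
back measure elevation against the 37 °C core, the unheated state of deep
lumbar tissue.  This single convention reconciles the fit with the
published predictions.  At $\Delta T = 0$ the model returns 0.317 L/min,
just above $F_o$, so resting tissue sits at a fold-change of ~1.02; the
ceiling is $F_{max}/F_o \approx 3.94$, the "four-fold" increase quoted as
the headline effect.

The flow unit is the L/min of the calibrating femoral artery applied
voxelwise; it should be read as a model output indexed to that vessel, not
as a literal volumetric flow of a voxel.  Fold-change is the unit-free
quantity to quote.

## Problem sizes used by the tests and scripts

The analysis scripts default to 2 mm voxels (≈750k unknowns, seconds per
solve); `scripts/acceptance.R` re-runs the two headline scenes at the
production 1 mm spacing (6M unknowns, a few minutes per scene).  The test
suite uses the 2 mm full phantom for the reproduction checks and smaller
scenes (down to a 1-voxel 1D column) for the verification suite.  The
sweep covers 45–65 °C in 5 °C steps, the device's stated range.

## What the synthetic phantom does and does not show

The phantom reproduces the *layered thermal physics* of the lumbar back:
conduction through skin and insulating fat, perfusion-limited penetration
into muscle, the competition between a diffuse warm mat and punctate hot
discs, and the saturating flow response.  Tests passing on it demonstrate
the solver and coupling are correct under these conditions.

It does not capture the individual geometry behind the original numbers: a
curved back surface, conformal roller contact, the two-lobed roller
footprint, and nine segmented tissues.  The practical consequence is a
consistent underestimate of actuator-induced elevation at depth on the
flat slab: at 2 cm under an actuator we obtain 38.4 °C (45 °C scene) and
41.7 °C (65 °C scene) against reported values of 39.6 and 45.5 °C, while
midline values (37.9 vs 38.3 °C at 2 cm, 65 °C scene) and the 3 cm probe
(39.2 vs 40.6 °C) track much closer.  Internal experiments with larger
stadium-shaped footprints and altered perfusion confirm the gap is a
contact-geometry effect, not a solver artifact; we deliberately keep the
documented 45 mm disc geometry rather than tuning the footprint to match.
The *relative* structure — exponential-like decay with depth, weak midline
response, flow saturation to ~4× at 2–3 cm for upper settings — is
reproduced throughout.

## Other numerical choices

* Voxel classification and surface-disc membership use voxel centers;
  boundaries are half-open.  A 45 mm disc sampled at 1 mm resolves its area
  to within 5 %.
* Extents that are not whole multiples of the spacing are rounded up to
  whole voxels.
* Ties in the multistart fit are broken by grid order; the first start is
  $(-1, 1)$.
* Degenerate inputs fail fast with informative errors: empty layer stacks,
  non-positive spacing, unregistered tissues, clipped or degenerate
  actuator placements, fewer than three calibration points, all-equal
  flows, and non-convergent solves (reported with the final residual).
* Configurations are validated against the full schema before any compute;
  unknown keys are rejected with their path, and a run directory is only
  written after the solve succeeds.

## Known limitations

* Steady state only: warm-up transients and pulsed protocols are out of
  scope, as is roller motion and mechanical deformation.
* The actuators are temperature patches, not meshed aluminum solids; this
  is exact for the steady quantities reported here but would matter for
  transients.
* Perfusion is fixed: the predicted flow increase does not feed back into
  $w_b$, matching the original one-way coupling.
* No tissue-damage (CEM43) metrics; the settings simulated sit in the
  comfort range.
* The slab geometry bias near the actuators discussed above.
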