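---
title: "Non-invasive pulmonary hemodynamics: models, phantoms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive pulmonary hemodynamics: models, phantoms and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pahemo)
```

## The problem

Pulmonary arterial hypertension (PAH) is diagnosed by an invasive right
heart catheterisation measuring mean pulmonary arterial pressure (mPAP >
20 mmHg). A promising non-invasive alternative chains together data that
routine care already produces: 4D-flow MRI gives the three-directional
velocity field in the pulmonary trunk over the cardiac cycle;
echocardiography gives a pressure estimate; and a patient-specific flow
simulation turns both into wall shear stress (WSS), whose time average
(TAWSS) correlates inversely with mPAP across PAH cohorts. `pahemo`
implements that workflow end to end as testable components:

1. **phantom** — synthetic 4D-flow studies of an idealised pulmonary
   bifurcation with an analytically known velocity field;
2. **segmentation** — vessel reconstruction by Boolean mask combination and
   MPA/LPA/RPA region labelling;
3. **flowquant** — inlet velocity profiles, flow waveforms, stroke volume,
   branch flow split, peak-systolic velocities;
4. **pressure** — simplified-Bernoulli and Chemla pressure estimates;
5. **windkessel** — three-element Windkessel (3EWK) tuning and 0-D
   simulation;
6. **rheology** — the Quemada shear-thinning blood viscosity law;
7. **solver** — pulsatile generalized-Newtonian flow in an axisymmetric
   tube with a 3EWK outlet;
8. **wss** — TAWSS at solver resolution and at 4D-flow voxel resolution;
9. **cohortstats** — the cohort regressions and validation metrics, plus
   `run_pipeline()` to orchestrate everything.

A seven-patient cohort of printed clinical values ships as a fixture
(`printed_cohort()`): cycle length, stroke volume, RPA flow fraction,
catheter mPAP, per-branch Windkessel parameters, paired 4D-flow/CFD
validation measurements, and regional TAWSS averages. All cohort-level
statistics in the package are recomputed from this table at run time.

## The synthetic phantom

No imaging data can be shipped, so every voxel-level operation is exercised
on phantoms with exact ground truth. A `phantom_spec()` describes a Y-shaped
vessel — a main pulmonary artery (MPA) along *z* splitting into left and
right branches in the *x–z* plane — plus the pulsatile flow conditions.

**Velocity field.** Each limb carries the axisymmetric Womersley solution
for its share of the inlet flow: the flow waveform is decomposed into
Fourier harmonics (`flow_harmonics()`), the zero-frequency harmonic gives a
Poiseuille profile and each oscillatory harmonic the classic Bessel-function
solution, normalised so the cross-sectional integral reproduces the
prescribed flow exactly. Complex-argument Bessel functions are evaluated
through Bessel's integral representation, which is accurate to near machine
precision at the Womersley numbers of pulmonary vessels (α ≈ 15–25). This
gives every downstream estimator an exact oracle: flux, wall shear rate and
plane velocities all have closed or quadrature-checkable forms.

**Defaults as study conditions.** The defaults mirror the clinical
acquisition the package emulates: 25 cardiac frames; voxel spacing
(2, 2.5, 2.5) mm; flow conditions per patient taken from the printed table
(e.g. period 0.95 s, stroke volume 95 mL, RPA fraction 0.62 for the first
patient). Values the clinical source does not state were fixed once at
realistic levels:

* **MPA radius 17.5 mm** (35 mm diameter) with branch radii 10.5/12 mm and
  branch angles 45°/40° — a dilated trunk typical of PAH;
* **VENC 2.0 m/s** — a common phase-contrast setting for pulmonary
  hypertension, where jets can approach 1.5 m/s; the generator refuses
  specifications whose analytic peak exceeds VENC rather than model
  aliasing;
* **waveform**: a half-sine ejection over one third of the cycle followed by
  zero diastolic flow, scaled to the stroke volume (configurable; any
  sampled waveform may be supplied);
* **kinematic viscosity** of the analytic field: the high-shear Quemada
  limit over a blood density of 1060 kg/m³.

**Partial-volume averaging.** Voxels within half a voxel diagonal of the
wall are averaged over a 3×3×3 sub-grid with zero velocity outside the
lumen. This reproduces the near-wall signal dilution that makes WSS
estimated directly from 4D-flow data biased low — the mechanism the `wss`
module quantifies. Gaussian velocity noise (`noise_sd`, seeded) is optional;
generation is bit-reproducible under a fixed seed.

What the phantom deliberately does **not** emulate: MRI physics (k-space,
eddy currents, phase wrapping), secondary/vortical flows at the bifurcation,
vessel curvature and wall motion. Passing tests therefore demonstrate
correct recovery of flow quantities from ideal laminar velocity data at
clinical resolution, not robustness to acquisition artefacts.

## Segmentation choices

The reconstruction mimics multi-mask workflows: each velocity component
"sees" the vessel segments where it dominates, and `combine_masks()` forms
the voxel-wise union with the magnitude mask. Cleanup uses 26-connectivity
(`largest_component()`), with size ties broken toward the component holding
the smallest voxel index in array order.

`label_regions()` must split the mask into MPA, LPA and RPA without manual
input. Marching along *z* from the inlet, the first cross-section whose
lumen is no longer singly connected bounds the bifurcation from above; but
two branch circles remain merged in-slice well past the anatomical
bifurcation. A second signal sharpens the estimate: at the bifurcation a
single dilated trunk gives way to two smaller branches, so the slice area
drops. The rule takes the first persistent >10% area drop relative to the
running proximal median, capped by the connectivity change; on default
phantoms the labels agree with ground truth for ≈99% of voxels. Separated
in-slice components are assigned left/right by centroid side relative to
the MPA centroid; merged cross-sections voxel-by-voxel by side. A
user-supplied bifurcation plane overrides everything (a straight tube with
a mid-plane hint labels proximal half MPA, distal half one branch). Planes
are specified in world millimetres with the origin at the volume corner;
voxel `[1,1,1]`'s centre is the geometry `origin`.

## Flow quantification choices

* **Interpolation**: trilinear in space everywhere; periodic linear in time
  when resampling profiles. In-plane sampling grids default to half the
  smallest voxel spacing.
* **Peak systole** is defined as the frame of maximum inlet volumetric flow
  — robust and independent of where velocities are probed.
* **Branch split** is normalised over the two branch flows so the two
  fractions sum to one exactly, matching how the measurement is reported
  clinically.
* **Plane-mean peak-systolic velocity** uses the velocity magnitude by
  default (`mode = "component"` gives the through-plane component); the
  clinical convention is ambiguous, so both are exposed.

On noiseless default-resolution phantoms of all seven printed patients the
chain recovers stroke volume within 0.5% and the RPA fraction within 0.001
— comfortably inside the 2% / ±0.02 bands the tests enforce.

## Pressure estimates

Peak PAP follows the simplified Bernoulli relation `4 v² + RAP` (v = peak
tricuspid regurgitant velocity, m/s; RAP in mmHg), mean PAP the Chemla
relation `0.61 · peak + 2`. Pulmonary hypertension is mPAP strictly above
20 mmHg. One constant, 133.322 Pa/mmHg, converts pressures everywhere.

## Windkessel tuning

`tune_3ewk()` fixes the total branch resistance from non-invasive targets,
`R_total = (mPAP_target − P_distal)/Q̄`, splits it into a proximal fraction
*f* and distal remainder, and sets the compliance from a prescribed time
constant, `C = τ/R2`. Back-deriving *f* and τ from the fourteen printed
branch parameter sets gives f ≈ 0.04–0.21 and τ = R2·C ≈ 0.60–0.72 s, so
the defaults `f = 0.1`, `τ = 0.7 s` sit mid-range; the distal (venous)
pressure defaults to zero, consistent with back-computing R_total from the
printed values. Note the printed per-branch parameters imply different
cycle-mean pressures for the two branches of the same patient (e.g. ≈38 vs
≈28 mmHg for the first patient), so the exact per-branch tuning inputs are
not recoverable; the tuner targets a single per-patient pressure and this
discrepancy is documented rather than reproduced.

`simulate_3ewk()` integrates `C dP_c/dt = Q − (P_c − P_d)/R2` with
fixed-step RK4 and reports `P = R1 Q + P_c` over all cycles. The startup
transient decays as `exp(−t/τ)`; with τ comparable to the period the 1%
cycle-to-cycle periodicity criterion is typically reached around cycle
five, which is why simulations run a *minimum* of three cycles and continue
until converged.

## Rheology

The Quemada model
`μ = μ_p (1 − k(γ̇) φ/2)⁻²`, `k = (k0 + k∞ √(γ̇/γ_c)) / (1 + √(γ̇/γ_c))`,
with literature constants μ_p = 1.32×10⁻³ Pa·s, φ = 0.45, k0 = 4.33,
k∞ = 2.07, γ_c = 1.88 s⁻¹ (all configurable). Shear rates are floored at
10⁻³ s⁻¹ to avoid the zero-shear blow-up in quiescent regions (with the
defaults, 0.5·k0·φ = 0.974, so the zero-shear viscosity is finite but three
orders above the high-shear limit). `viscosity_bounds()` exposes both
limits; the high-shear value μ∞ ≈ 4.63×10⁻³ Pa·s is the reference viscosity
for Reynolds/Womersley numbers and for voxel-grade WSS.

## The pulsatile solver

Patient-specific 3-D CFD is out of scope; the solver's role is to exercise
the simulation methodology — shear-thinning rheology, 3EWK coupling,
periodicity control, WSS extraction — in a geometry with exact analytic
ground truth: a straight rigid axisymmetric tube.

**Discretisation.** Staggered (r, z) finite volumes: axial velocity on
z-faces, radial velocity on r-faces, pressure at cell centres; default grid
32 × 48. An incremental pressure-projection (fractional-step) scheme
advances each step: explicit first-order upwind convection (negligible in
the fully developed oracle flows), θ-implicit viscous terms with viscosity
evaluated from the previous step's shear-rate field, a pressure Poisson
solve with Neumann conditions (factorised once), and a divergence-free
correction. The viscous operator uses the generalized-Laplacian form
∇·(μ∇u), exact for the parallel flows the oracles probe. The wall face uses
a one-sided second-order gradient through the no-slip wall, which makes the
discrete steady state exact for parabolic profiles and keeps the wall
shear-rate trace (extracted with the matching one-sided difference)
second-order accurate.

**Time integration.** θ = 0.5 (Crank–Nicolson) by default: at the reference
step of 0.005 s a first-order scheme's transfer error (≈ ω·dt ≈ 4%) would
dominate the Womersley error budget, while CN keeps it below 0.2%. θ is
configurable (θ = 1 gives backward Euler). Because convection is explicit,
the internal step is reduced below the configured `dt` whenever the
advective CFL limit (0.45·Δz/U_peak) requires it, and the inlet ramps up
smoothly over the first half cycle to avoid an impulsive start; the final
(analysed) cycle is unaffected. A CFL violation or non-finite field aborts
with a named error.

**Boundary conditions.** The inlet profile is either Womersley-reconstructed
from a flow waveform or an axisymmetrised measured `inlet_profile`; the
wall is rigid no-slip; the outlet copies the axial profile (zero gradient),
is corrected to exact global mass balance each step, and its pressure level
is set by the coupled 3EWK advanced with the same step. Cycles repeat until
the outlet-pressure periodicity metric `100·max|a−b|/max|b|` drops below
1% (configurable), up to `n_cycles_max`.

**Verified behaviour** (enforced in tests at the tolerances shown): steady
Poiseuille profile and WSS = 4μQ/(πR³) to well below 2–3%; single-harmonic
Womersley velocity and wall shear within 5% L2 at the default grid (in
practice ≈0.1–0.6%); instantaneous mass conservation to machine precision;
a steady Quemada run within 3% of an independent 1-D generalized-Newtonian
boundary-value oracle; geometric periodicity decay at rate e^(−T/τ).

**Flow regime.** `assess_flow_regime()` computes the peak Reynolds number
and the Womersley number α = (D/2)√(2πρ/(μT)) and applies the empirical
large-artery transition criterion Re < 150α. Statements of this criterion
sometimes conflate α with the angular frequency 2π/T; the package uses the
standard dimensionless definition and reports both Re and 150α rather than
asserting a regime, warning when the criterion is exceeded.

## WSS at two resolutions

`wall_shear_stress()` evaluates τ_w = μ(γ̇_w)·γ̇_w from the solver's wall
shear-rate trace; `tawss()` time-averages |τ_w| over one cycle
(trapezoidal, periodic); `regional_average()` forms area-weighted means
over region sets — the whole geometry versus the MPA alone, the two
averages the cohort regressions use.

`voxel_wss_estimate()` mimics WSS estimation directly from clinical
4D-flow data: at each wall patch (limb × axial station × angle) the
limb-axial velocity is sampled at the nearest `fit_depth` lumen voxels
along the inward normal and regressed against wall distance with the
intercept pinned to zero at the known sub-voxel wall position; the slope
times a Newtonian reference viscosity gives WSS. Wall distance is measured
radially in the limb frame so the dominant error is resolution, not
registration; coarse data cannot support shear-dependent viscosity, hence
the Newtonian μ∞, matching common 4D-flow practice. For a parabolic
profile a single sample at depth *d* underestimates the true gradient by
exactly (1 − d/(2R)); partial-volume dilution adds to the bias. On the
default phantom the voxel estimate recovers ≈49% of the analytic TAWSS at
1 mm voxels, ≈26% at 2.5 mm and ≈14% at 5 mm — strictly below the fine
value and monotone in voxel size, the same direction and order of magnitude
as the published gap between plane-based 4D-flow TAWSS and CFD TAWSS
(means of ≈0.1 Pa versus ≈1.5 Pa). Reproducing those absolute plane values
would require the real scans and the commercial tool; only the mechanism is
in scope.

## Cohort statistics

`linear_fit()` is ordinary least squares via `stats::lm()`, with R²
reported as the squared Pearson correlation and rounded to two decimals
when compared against printed values (raw doubles are retained everywhere
else, including JSON output). On the printed cohort the whole-geometry
TAWSS–mPAP regression gives R² = 0.843 (printed: 0.84) with slope
−11.6 mmHg/Pa; the MPA-only regression gives R² = 0.764, which rounds to
0.76 against a printed 0.77 — the published value evidently used unrounded
TAWSS inputs, and the package reports the honest recomputation. The
stroke-volume regression recomputes to R² = 0.714 against a printed 0.69,
and the diameter regression (printed R² = 0.36) cannot be recomputed at all
because the diameters are not published; both are therefore implemented but
not treated as reproduction targets, and the diameter regression runs only
on synthetic cohorts. `validation_metrics()` recomputes the per-patient
CFD-vs-4D-flow agreement (velocity differences 5–19%, mean 10.4%; RPA
fraction differences ≤ 0.02).

`generate_synthetic_cohort()` draws cohorts with a known linear TAWSS–mPAP
rule (defaults echo the printed cohort: slope −11.6 mmHg/Pa, intercept
68.2 mmHg, 5 mmHg Gaussian noise, TAWSS uniform on 0.6–3.7 Pa) for
parameter-recovery checks: with n = 200 the fitted slope lands within three
standard errors of truth.

`run_pipeline()` orchestrates either the fixture-mode analyses or the full
phantom chain (study → segmentation → flow quantities → Windkessel tuning →
voxel and analytic TAWSS → optional tube simulation), writing a cohort CSV,
a regression JSON and a stage-timing log.

```{r example}
res <- run_pipeline(pipeline_config(mode = "fixture"))
res$correlations[, c("predictor", "slope", "r_squared")]
ggplot2::autoplot(linear_fit(printed_cohort(), tawss_whole_pa, mean_pap_mmhg))
```

## Problem sizes and numerical tolerances

The test suite and the acceptance script run phantoms at the clinical
spacing (≈30×20×40 voxels × 25 frames), solver grids of 16–48 radial and
8–48 axial cells over 3–10 cardiac cycles, and the voxel-bias sweep at
{1, 2.5, 5} mm. These sizes were chosen so each check isolates one source
of error (quadrature, discretisation, resolution bias) while remaining
deterministic; all stochastic steps take explicit seeds. Key numerical
constants: shear-rate floor 10⁻³ s⁻¹; periodicity tolerance 1%; CFL budget
0.45; pressure gauge pinned so the area-mean outlet pressure equals the
Windkessel value.

## Known limitations

* The solver is axisymmetric: bifurcation secondary flows, curvature and
  jet impingement — visible in patient studies — are represented only
  through the phantom's per-limb fields, not simulated.
* Rigid walls: compliant wall motion would lower WSS somewhat, though less
  so in PAH where arteries stiffen.
* The phantom's Womersley field is laminar and unidirectional; regurgitant
  or vortical flow appears only as signed waveform lobes.
* Echo inputs (tricuspid velocity, RAP) are not published per patient, so
  pipelines use synthetic echo values or target pressures directly.
* With n = 7 the cohort correlations are indicative, not inferential; no
  p-value machinery beyond OLS is provided by design.
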