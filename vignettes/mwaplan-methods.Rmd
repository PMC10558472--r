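---
title: "Methods: the mwaplan thermal-ablation planning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mwaplan thermal-ablation planning model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mwaplan predicts the coagulated volume of a percutaneous microwave ablation
(MWA) in liver and evaluates that prediction the way a retrospective
validation study would: per-case overlap and surface-distance metrics
against a ground-truth ablation, and cohort-level statistics against a
manufacturer baseline. This vignette is the package's own account of the
model, its parameters, the numerical choices, and what the synthetic
phantoms can and cannot demonstrate.

## The bioheat model

Temperature on a regular voxel grid follows the Pennes bioheat equation

$$\rho C_p \frac{\partial T}{\partial t} =
  \nabla \cdot \lambda \nabla T +
  \omega_b \rho_b C_{p_b} (T_b - T) + Q_{appl},$$

with liver density $\rho$, specific heat $C_p$, conductivity $\lambda$, and
a perfusion sink that relaxes tissue toward arterial blood temperature
$T_b$. Three couplings make it an ablation model rather than a heat
equation:

**Perfusion and the vessel heat sink.** The distributed perfusion rate is
damage-modulated, $\omega_b = \omega_0 e^{-\Omega}$: perfusion ceases
smoothly as the capillary bed coagulates. The literature this behaviour
descends from describes cessation qualitatively; the exponential form was
chosen because it is smooth, parameter-free given $\Omega$, and testable
(the limit $\Omega \to \infty \Rightarrow \omega \to 0$ is asserted in the
test suite). A hard step at $\Omega = 1$ is available via
`blood_model(shutdown = "step")`. On segmented vessel voxels the rate is
*multiplied* by `vessel_enhancement` (default 50), representing the lower
flow resistance of larger vessels relative to capillaries. Whether such a
sink should replace or multiply the distributed term is genuinely open; we
chose multiplicative coupling (so vessel perfusion also shuts down when the
vessel wall itself coagulates) and flag it as a modelling decision. The
perfusion domain is the liver mask; voxels outside the liver conduct but do
not perfuse.

**Water evaporation.** The latent heat of the tissue water content
(`water_fraction` = 0.778, latent heat 2.26 MJ/kg) is spread as a rectangle
over the 99–100 °C band of the specific heat, so enthalpy is a continuous,
strictly increasing, piecewise-linear function of temperature. The solver
advances *enthalpy*, not temperature (see Numerics), which makes the latent
plateau robust and energy accounting exact.

**Applicator source.** $Q_{appl}$ is a simplified axisymmetric deposition
about the applicator axis: flat along the active zone (default 10 mm)
with Gaussian axial tapers (`axial_taper`, default 4 mm) and Gaussian
radial falloff (`radial_scale`, default 3.5 mm), normalized on the actual
grid so its integral is `efficiency * power` at baseline temperature. A
sigmoidal absorption multiplier decays from 1 to `absorption_floor`
(default 0.2) across the evaporation band, standing in for the reduced
microwave absorption of desiccated tissue. Any axisymmetric two-parameter
family reproducing ellipsoidal ablations would serve; this one is declared
in configuration and recovered by calibration, which is the property that
matters.

**Damage.** Arrhenius dose $\Omega = \int A e^{-E_a/(RT)}\,dt$ with liver
coagulation constants $A = 7.39\times10^{39}\,\mathrm{s^{-1}}$,
$E_a = 2.577\times10^5$ J/mol, threshold $\Omega \ge 1$ (the 63.2%
denaturation convention). All constants are configurable and recorded in
output manifests. A known property of this constant pair is a small but
nonzero dose at body temperature (about 0.18 over 10 minutes — far below
threshold, but visible as a mild perfusion drift through $e^{-\Omega}$);
tests assert the computed value rather than pretending it is zero.
Sequential ablations are independent: temperature resets to `T_init`
between them, each ablation's damage field is thresholded separately, and
the per-ablation masks are united.

## Numerics

- **Scheme.** 7-point finite differences on the uniform grid. The explicit
  scheme advances diffusion + source in enthalpy form (exactly
  conservative: the adiabatic test recovers deposited energy to machine
  precision) and applies the perfusion term as an *exact exponential
  relaxation* toward $T_b$ each step (Lie splitting). The relaxation
  sub-step is unconditionally stable and reproduces the perfusion-only ODE
  exactly, so the stability bound contains only the diffusive term:
  $dt \le \rho C_p / (2\lambda \sum_i h_i^{-2})$, enforced with the
  band-free $C_p$ (conservative, since the band capacity is larger).
  Violations are a configuration error, never a silent blow-up.
- **Boundaries.** Ghost cells: Dirichlet faces place the wall half a voxel
  outside the boundary voxel center (`ghost = 2 T_w - T`), which keeps the
  scheme second order — the perfused-slab test converges at roughly second
  order against its cosh/sinh closed form. Insulated faces mirror. Axes of
  size one carry no flux, which is how the 1D verification problems run in
  the 3D solver.
- **Implicit option.** Backward Euler with coefficients lagged at the
  current temperature, solved sparsely (Matrix). Unconditionally stable;
  used for cross-verification (agreement within 0.5 °C on a reference
  case), not for production runs.
- **Compiled kernels.** The production time loop (stepping, absorption,
  perfusion shutdown, Arrhenius accumulation) and the exact separable
  Euclidean distance transform are C++ (Rcpp). The R stepper is the
  readable reference; a test pins the two to each other at 1e-12.
- **Degenerate inputs.** Empty masks are errors where a metric would be
  undefined (two empty masks in Dice, empty surfaces); zero power yields a
  zero field; `dt = 0` leaves damage unchanged.

## Calibration

`calibrate_source()` fits `efficiency` and `radial_scale` by Nelder–Mead on
log-parameters, minimizing the mean squared relative mismatch between
simulated homogeneous-tissue ablation dimensions and the tabulated ones.
The objective uses the four corners of the (power, duration) lattice —
short durations pin the deposition shape, long durations the deposited
power — and the returned fit table verifies every row. Ablation dimensions
are measured by `ellipsoid_dimensions()` (axial extent; diameter from the
central slab), deliberately the same estimator used to build the synthetic
table, so calibration against that table is a genuine inverse-crime
recovery test. The dimension estimator is quantized at the voxel level,
which leaves a shallow valley in the objective; recovery of `efficiency` is
therefore good to roughly the 10% level at 2 mm resolution while the
post-fit dimensional residuals are a few percent.

## The synthetic phantoms

The phantom module emulates the conditions of a liver MWA validation
cohort: 1–6 sequential ablations per case, powers in {80, 90, 100} W
(predominantly 80 W), durations of 3–10 min, and per-case vascular
fractions spanning 0–22.2%. The vascular-fraction targets are drawn from a
21-value empirical list covering that range; for cohorts of up to 21 cases
they are sampled without replacement so the range is actually spanned.
Artifact flags (applicator misalignment, infarction wedge) default to a
rate of 0.1 each. These defaults are the study conditions; they are not
tuned.

- **Livers** are voxelized ellipsoids (default semi-axes 50 × 42 × 36 mm,
  ±6% jitter) on a 2 mm grid — coarse enough that a full two-arm 20-case
  replay runs in minutes on one core, fine enough that Dice and AAE are
  meaningful at the 1 mm-class resolution the metrics target. 1 mm grids
  are supported and used in the metric tests.
- **Vessel trees** bifurcate recursively with Murray's-law radii
  ($r^3$-conserving, symmetric split), seeded angular jitter, cylinders
  clipped to the liver, and growth stopped below 0.5 mm radius (branches
  of that class carry no relevant cooling). Random draws happen in
  breadth-first order so tree volume is monotone in the generation count.
  A straight feeder vessel through the first applicator's neighbourhood is
  bisected in radius until the vascular fraction hits its target within
  one percentage point.
- **Ground truths** are model predictions (sink enabled) eroded within
  3 mm of vessels — a fixture device emulating heat-sink indentation, not
  a physical claim; the depth is configurable. The wedge injector unions a
  cone from the ablation surface to the nearest liver-capsule point
  (infarction reaching the capsule); the misalignment injector applies a
  seeded rigid transform with nearest-neighbour resampling. Both corrupt
  the *ground truth*, mirroring how these artifacts corrupt segmented
  necrosis in retrospective data, never the model.

**What passing phantom tests show — and what they do not.** The phantoms
verify the solver against closed forms, the metrics against brute-force
oracles, and the full pipeline's discriminative pattern: with the vessel
sink disabled the model tracks the manufacturer table closely (volume
correlation above 0.99) with no vascular-group effect, and with the sink
enabled the above-5% vascular-fraction group shows a significantly negative
identity-line deviation while every case's volume shrinks. They do not
validate the model against real necrosis: there is no CT intensity
simulation, no real vessel-segmentation noise, no tissue shrinkage or
swelling, no vascular occlusion dynamics, and the ground-truth distortion
model is schematic. Clinical-scale headline numbers require clinical data.

## Statistics

The pre-specified cohort contrast is a Tukey 95% range test (via
`stats::aov` + `stats::TukeyHSD`) on the identity-line distance
$(y - x)/x$ of model vs manufacturer volumes, between cases above and below
the 5% vascular-fraction threshold. The threshold is configurable — whether
it is pre-specified or scanned is left to the analyst; the replay treats 5%
as the default. Only this one contrast is tested, so no multiplicity
correction applies. Correlations on scatter data are Pearson's r. Whisker
summaries use the standard Tukey boxplot statistics
(`grDevices::boxplot.stats`), and paired model-minus-manufacturer mean
differences accompany each indicator. With two groups the Tukey interval
coincides with the pooled-variance t interval; the test suite cross-checks
significance calls against a permutation oracle.

## Problem sizes

Verification problems are deliberately small: 1D slabs of 20–40 voxels,
conservation boxes of $15^3$, metric grids of $31^3$–$41^3$ at 1 mm,
calibration and cohort grids at 2 mm (about $6\times10^4$–$3\times10^5$
voxels), 20-case cohorts. These sizes were chosen so the whole verification
suite and the acceptance script each complete in minutes on a single core
while leaving every asserted tolerance comfortably resolvable.

## Known limitations

- The deposition family and absorption sigmoid are stand-ins for an
  electromagnetic solution; only their calibrated, ellipsoid-reproducing
  behaviour is claimed.
- Perfusion temperature dependence is reduced to damage coupling; explicit
  $\omega(T)$ forms from the perfusion literature are not implemented.
- Vessel voxels relax toward $T_b$ through an enhanced rate; there is no
  flow direction, no downstream warming, no occlusion model.
- Masks, surfaces and distances are voxel-based (surface voxels at voxel
  centers); no marching-cubes surfaces. At 1 mm spacing the stated ±1 voxel
  tolerances absorb this.
- The manufacturer table shipped with the package is synthetic (generated
  by the forward model); real vendor tables can be supplied as CSV with
  columns `power_W, duration_min, length_mm, diameter_mm`.
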