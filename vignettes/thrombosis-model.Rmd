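---
title: "A shear-driven thrombosis model for the dissected aorta: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shear-driven thrombosis model for the dissected aorta: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fltsim)
```

## The problem

In type B aortic dissection the intimal flap divides the aorta into a true
lumen (TL) and a false lumen (FL) connected through an entry and a re-entry
tear. Whether and where the FL thromboses is prognostic: complete false-lumen
thrombosis (FLT) is protective, partial FLT is associated with late
complications. `fltsim` is a desk-scale, two-dimensional simulator of FLT in
an idealized dissection, with two-way coupling between pulsatile blood flow,
a mobile intimal flap, and a continuum thrombosis model whose growing clot
obstructs the flow.

The geometry is a planar analog of the tube-in-tube configuration: a TL
channel (width 19.4 mm) running from inlet to outlet, an FL channel (width
23 mm) closed at both extremities, and a 0.8 mm flap between them interrupted
by two 10 mm tears. Widths stand in for the lumen diameters. Axial dimensions
(dissected length 200 mm, tears inset 12.5% of the dissected length from each
FL extremity, 40 mm inlet/outlet extensions) are configuration parameters
with documented defaults, since only the cross-sectional dimensions are fixed
by the idealized geometry.

## The thrombosis model

Four species are tracked. Resting platelets (RP) and activated platelets
(AP) are relative (dimensionless) concentrations advected by the flow and
diffusing with $D_{RP} = 1.6\times10^{-13}$ and
$D_{AP} = 1.6\times10^{-11}\ \mathrm{m^2/s}$. The coagulant $C$ (nmol/L) is
*diffusion-only* — it is never advected — with effective diffusivity
$D_C = 10^{-8}\,\phi_{\dot\gamma}\ \mathrm{m^2/s}$. Bound platelets BP
(nmol/L), the growing thrombus, are immobile: a pure local ODE.

Reactions are gated by sigmoidal switching functions
$\phi(x) = x^2/(x^2 + x_t^2)$:

$$S_{RP} = k_{RP}[AP][RP], \quad S_{AP} = k_{AP}[AP][RP],$$
$$S_C = k_{C1}\,\phi(BP)\,[AP] + k_{C2}\,\phi(C)\,[AP]\,(1-\phi_{\dot\gamma}),$$
$$S_{BP} = k_{BP}\,\phi(AP)\,\phi(C)\,\phi_{\dot\gamma}\,[AP],$$

with $k_{RP} = -0.15\ \mathrm{s^{-1}}$, $k_{AP} = 3.0\ \mathrm{s^{-1}}$,
$k_{C1} = 16$, $k_{C2} = -6$, $k_{BP} = 12\ \mathrm{nmol\,L^{-1}s^{-1}}$ and
thresholds $\dot\gamma_t = 50\ \mathrm{s^{-1}}$, $AP_t = 15$, $C_t = 10$,
$BP_t = 20\ \mathrm{nmol/L}$. These kinetics are deliberately accelerated so
clot growth completes within tens of cardiac cycles rather than days; they
are rate dials, not physiological constants.

The shear switch is implemented in the dimensionally consistent form
$\phi_{\dot\gamma} = \dot\gamma_t^2 / (\dot\gamma^2 + \dot\gamma_t^2)$, which
is 1 in stasis and 1/2 at the threshold. (The mixed-unit variant
$\dot\gamma_t^2/(\dot\gamma + \dot\gamma_t^2)$ that sometimes appears in
print is available via `literal_shear_switch` for sensitivity checks; it has
no consistent units and moves the half-activation point to
$\dot\gamma_t^2 = 2500\ \mathrm{s^{-1}}$.)

The cascade is wall-seeded: the coagulant receives an inward wall flux of
magnitude $k_{c,wall} = 16$ on facets where the *previous cycle's*
time-averaged wall shear stress (TAWSS) is below 0.15 Pa **and** the local
BP is still below $BP_t$. RP and AP take a fixed relative wall value of 2;
BP has zero wall flux. Because $S_C$'s production term requires $BP > 0$ and
its consumption term requires $C > 0$, the cascade cannot self-start
anywhere the wall flux never fires — this is what keeps the fast-swept TL
patent while the stagnant FL clots, and it is asserted as an invariant in
the test suite.

Two unit conventions in the published tables are internally inconsistent and
are implemented verbatim: AP is dimensionless while $C_t, BP_t$ are nmol/L
(so $S_C$, $S_{BP}$ carry nmol/(L s) with a dimensionless AP multiplier),
and $k_{c,wall}$ is printed per meter. For the latter the discrete boundary
condition needs a length to convert the printed constant into a flux
density; we use an uptake length $\delta_c$ (`c_wall_delta`, default 1 mm,
the flap-thickness scale), giving a wall-cell source of
$k_{c,wall}\,\delta_c/\Delta y \approx 13\ \mathrm{nmol\,L^{-1}s^{-1}}$ at
the default resolution — commensurate with $k_{C1}$, which is consistent
with the model's design intent of wall seeding at reaction-comparable rates.

### Feedback on the flow

Thrombus resists flow through a Brinkman-type momentum sink
$$F = k_M\,\frac{BP^2}{BP^2 + BP_t^2}\,u, \qquad k_M = 10^7\ \mathrm{kg\,m^{-3}s^{-1}},$$
subtracted from the momentum balance. At $BP = BP_t$ the drag is half of
saturation; fully thrombosed regions behave like a low-permeability porous
plug (the verification suite checks the channel flux against the closed-form
Brinkman solution). The sink is treated implicitly — explicitly it would
demand $\Delta t < \rho/k_M \approx 10^{-4}$ s.

## Hemodynamics

Blood is incompressible with $\rho = 1060\ \mathrm{kg/m^3}$ and Quemada
shear-thinning viscosity at 45% hematocrit,
$$\mu = \mu_p\left(1 - \tfrac12 k(\dot\gamma) H\right)^{-2},\quad
k = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}{1 + \sqrt{\dot\gamma/\dot\gamma_c}}.$$
The default constants ($\mu_p = 1.32$ mPa s, $k_0 = 3.94$,
$k_\infty = 1.77$, $\dot\gamma_c = 4.80\ \mathrm{s^{-1}}$ at $H = 0.45$) are
the Cokelet-fit parameterization of whole blood; they give a high-shear
asymptote of 3.6 mPa s and a zero-shear viscosity of 0.10 Pa s. A
$10^{-6}\ \mathrm{s^{-1}}$ floor inside the square root keeps derivatives
bounded in stagnant regions; its effect on the viscosity is below 0.5% and
only exactly at zero shear.

The inlet imposes a flat velocity profile following an aortic-like waveform
at 1.02 Hz — one systolic peak, a short early-diastolic reverse phase —
stored as a truncated Fourier series so it is smooth and exactly periodic.
The default cycle-mean velocity is 0.10 m/s, chosen so the TL Reynolds
numbers match the regime the model targets (mean $\approx 450$, peak
$\approx 2700$); the corresponding mean TL wall shear stress sits a factor
of ~2 above the 0.15 Pa TAWSS gate, which is what keeps the TL patent. The
TL outlet couples to a three-element Windkessel
($C\,dP_{wk}/dt = Q - P_{wk}/R_p$, $P = P_{wk} + QR_c$, backward-Euler)
whose per-unit-depth defaults put the outlet pressure in a physiological
80–120 mmHg band; the FL ends are no-slip walls. Windkessel constants and
the waveform shape are documented placeholders — the idealized-geometry
literature does not pin them — and everything is overridable in the
configuration.

### Discretization

The solver is a staggered-grid (MAC) finite-volume projection method on a
tensor-product mesh: uniform axial spacing, banded transverse spacing with
the flap strip always resolved by at least three rows snapped to its faces.
Solid regions — the exterior of the vessel and the flap — are represented by
volume penalization: a large implicit sink $k_{pen}(u - u_s)$ with
$k_{pen} = 10^8\ \mathrm{kg\,m^{-3}s^{-1}}$, one decade stronger than mature
clot, with fractional cell occupancy so the flap can move smoothly across
the fixed grid. The same implicit machinery applies the thrombus sink.

Momentum advection uses conservative MUSCL fluxes with the van Leer limiter
(explicit); viscous terms are explicit in x and line-implicit in y (Thomas
solves), which removes the step restriction from the thin flap rows; wall
viscous fluxes use a quadratic-consistent one-sided gradient that makes the
discrete Poiseuille solution and its wall shear stress exact. Pressure is an
incremental projection: the predictor carries the old pressure gradient, a
conjugate-gradient Poisson solve (matrix-free, Jacobi-preconditioned,
warm-started) yields the increment, and Dirichlet boundaries (outlet/
pressure-driven benchmarks) enter through half-cell fluxes. The scheme is
first-order in time and second-order in space; the verification suite holds
it to <1% on Poiseuille, <3% $L_2$ on Womersley, <2% on the Brinkman plug
flux.

Species transport uses the same fluxes with Heun (RK2) time stepping
(second order, which the advected-Gaussian oracle requires), explicit
diffusion, and positivity-preserving Patankar splitting for the reactions —
sinks are divided through, sources added explicitly — so RP, AP, C stay
non-negative and BP is non-decreasing by construction. The convective CFL
target is 0.4; defaults of 1600–2400 steps per cycle keep the peak-systolic
tear jets inside it.

## The reduced-order flap

The paper-scale alternative — monolithic 3D fluid–structure interaction —
costs months of compute. Here the flap is a quasi-static clamped–clamped
Euler–Bernoulli beam loaded by the transmural pressure difference sampled on
its two faces, zero load across the tears. A planar beam alone would be
absurdly soft: a 0.8 mm × 200 mm strip deflects meters per kPa, because the
planar reduction discards the circumferential bending restraint of the real
flap, which is clamped along its longitudinal edges and spans only ~23 mm
across the vessel. We restore that restraint as a Winkler foundation
$k_f = 384 D / b^4$ with plate rigidity $D = E t^3/(12(1-\nu^2))$ and
$b$ the FL width — the distributed stiffness of a clamped strip of that
span. With $E = 6.75$ MPa this gives millimeter-scale excursions under
kPa-scale transmural loads, the regime the 3D flap actually operates in.
Both the beam and the foundation scale linearly with $E$, so displacement
is exactly proportional to $1/E$ and the rigid/stiffer (60 MPa)/flexible
(6.75 MPa) presets order as expected.

The flap is updated once per time step from the instantaneous load with
under-relaxation 0.02. Stronger coupling (the naive 0.5) is violently
unstable here: the FL is a closed incompressible cavity, so the added-mass
pressure reaction to any flap motion is immediate and large, and the
partitioned loop diverges within ten steps. The relaxation acts as a
first-order filter with a ~20 ms time constant — far below the 250 ms
systolic timescale, so the flap still tracks the load quasi-statically.
Its displacement cap (40% of the narrower lumen) is a mesh-safety bound
well above physical excursions.

## Cycle bookkeeping and outputs

A per-cycle ledger accumulates |WSS| on every boundary facet and shear
rate, AP and viscosity per cell; at each cycle boundary it publishes the
cycle averages and swaps the TAWSS buffer that gates the coagulant wall
flux during the next cycle. During the very first cycle (and the flow-only
pre-cycles, default 2–3 standing in for the paper-scale 15) the published
TAWSS is $+\infty$, i.e. the wall flux is off until one developed cycle has
been averaged. Thrombus "volume" is the area with $BP \ge BP_t$ times a
1 m unit depth, reported in cm³; $BP_t$ is the model's only BP threshold
(it also half-saturates the momentum sink), so it doubles as the thrombus
cut. Post-processing includes vorticity and the 2D $\lambda_2$ vortex
criterion (the lower eigenvalue of $S^2+\Omega^2$, flagged below
$-10\ \mathrm{s^{-2}}$), TL–FL pressure differences on proximal/middle/
distal cuts, growth-phase segmentation (lag / accelerated / plateau split
at 10% of the peak growth rate — the phases are named in the literature
but not quantified, so the 10% rule is artifact-defined), and the
regression of plateau volume on maximum flap displacement across stiffness
presets.

## Problem sizes and what the tests show

The verification oracles run on channels of 10–100 cells per dimension in
seconds. The end-to-end "mini dissection" used by the regression tests is a
90 mm dissected segment with 15 mm extensions on a ~3,000-cell mesh
(1.25 mm axial, 1.6 mm transverse in the channels, 0.27 mm across the
flap), 2400 steps per cycle, 2 pre-cycles plus 12 thrombosis cycles —
about three minutes per run on one core. At these sizes the simulations
reproduce the mechanistic pattern of FLT qualitatively: thrombus initiates
in the stagnant pockets at both FL extremities while the jet-washed
inter-tear belly and the TL stay patent, and the volume trace shows a clear
time-lag followed by an accelerated phase.

Known limitations at desk scale, in honest terms:

* **No plateau within the test budget.** Growth is still in its accelerated
  phase after 12–20 cycles; reaching the no-further-growth plateau (and the
  >50% FL fill after which flap motion should visibly decay) requires
  several times more cycles than the test tier runs. The phase-segmentation
  machinery is therefore verified against closed-form logistic traces, and
  the plateau-dependent comparisons are reported as directions, not
  magnitudes.
* **A TL-side stagnation pocket.** Just distal of the re-entry jet the 2D
  geometry shelters a small TL region whose TAWSS falls below the gate, so
  a patch of TL thrombus can appear there late in a run. In 3D the flow
  wraps around the flap and washes this pocket; in 2D it cannot. The FL
  pattern is unaffected.
* **2D jets are stronger than 3D jets.** A planar jet cannot spread
  laterally, so tear jets wash the FL belly relatively harder than in a
  tube; FL filling is correspondingly slower and more end-dominated than
  the 3D reference behavior.
* The outer walls are rigid (only the flap moves), there is no lysis, no
  residence-time species, and platelet margination is not modeled.

## Reproducing the study conditions

`simulation_config()` carries every model constant with its default;
`mini_dissection_config()` is the desk-scale variant;
`run_comparison()` runs the rigid / stiffer / flexible presets and fits the
displacement–volume regression. `scripts/acceptance.R` re-evaluates the
model-constant limit identities (source terms, switch midpoints, sink
half-saturation, gated wall flux) through the installed package and writes
them as JSON.
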