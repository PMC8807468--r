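# fltsim

Simulation of false-lumen thrombosis (FLT) in idealized type B aortic
dissection, for researchers studying how intimal-flap mobility and local
hemodynamics shape clot growth. The package couples, in two dimensions:

* a pulsatile incompressible flow solver (staggered-grid projection method)
  with Quemada shear-thinning blood rheology, a flat-profile aortic inlet
  waveform and a three-element Windkessel outlet;
* a mobile intimal flap, modeled as a quasi-static pressure-loaded
  clamped beam on an elastic foundation, moving through the fixed grid as a
  penalized solid band;
* a four-species shear-driven thrombosis model — resting platelets (RP),
  activated platelets (AP), coagulant (C, diffusion-only) and bound
  platelets (BP, immobile) — with sigmoidal switching functions
  φ(x) = x²/(x² + x_t²), a TAWSS-gated coagulant wall flux
  (on where previous-cycle TAWSS < 0.15 Pa and BP < BP_t), and source terms

      S_RP = k_RP [AP][RP]            k_RP = −0.15 s⁻¹
      S_AP = k_AP [AP][RP]            k_AP =  3.0  s⁻¹
      S_C  = k_C1 φ(BP)[AP] + k_C2 φ(C)[AP](1 − φ_γ̇)
      S_BP = k_BP φ(AP) φ(C) φ_γ̇ [AP] k_BP = 12 nmol L⁻¹ s⁻¹

  where φ_γ̇ = γ̇_t²/(γ̇² + γ̇_t²) confines deposition to low shear;
* two-way feedback: growing thrombus drags on the flow through a
  Brinkman-type momentum sink F = k_M · BP²/(BP² + BP_t²) · u with
  k_M = 10⁷ kg m⁻³ s⁻¹.

The result is a desk-scale tool for rigid-flap vs compliant-flap
comparisons of thrombus growth: where the clot initiates, how the volume
trace segments into lag / accelerated / plateau phases, and how plateau
volume relates to maximum flap excursion.

## A worked example

Evaluate the model operators at a few canonical points:

```r
library(fltsim)
p <- thrombosis_params()
source_terms(RP = 1, AP = 1, C = 0, BP = 0, phi_gamma = 1, p)$S_AP
#> [1] 3
shear_switch(50, p)          # half-activation at the shear threshold
#> [1] 0.5
coagulant_wall_flux(tawss = 0.10, BP = 5, p)   # gate open
#> [1] 16
fictitious_force(BP = 20, u = 1)               # half of k_M
#> [1] 5e+06
```

Run the desk-scale dissection and the flap-stiffness comparison:

```r
cfg <- mini_dissection_config()        # 90 mm dissected segment, ~3k cells
cmp <- run_comparison(cfg, presets = c("rigid", "stiffer", "flexible"))
cmp$summary
#>     preset max_displacement_mm plateau_volume_cm3 fl_fraction termination
#> 1    rigid          0.00000000           355.9744  0.06944444 cycles done
#> 2  stiffer          0.03884109           397.6218  0.08425926 cycles done
#> 3 flexible          0.35137574           622.9167  0.15462963 cycles done
cmp$regression[c("slope", "intercept", "r_squared")]
#> $slope      [1] 745.4915
#> $intercept  [1] 362.0643
#> $r_squared  [1] 0.9981997
```

Thrombus volume (cm³ at a 1 m unit depth) grows monotonically with flap
mobility: the flexible flap (E = 6.75 MPa, 0.35 mm peak excursion) deposits
~75% more thrombus than the rigid comparator over the same 12-cycle
protocol, and the volume–displacement relation is linear (R² ≈ 0.998) —
the mechanistic signature the model is built to probe. (~10 min for the
three runs on one core.)

`run$volume` holds the thrombus-volume trace (time, cm³, FL fraction);
`growth_phase_segmentation(run$volume$time, run$volume$volume_cm3)` splits
it into time-lag / accelerated / plateau phases. Thrombus initiates in the
stagnant pockets at both FL extremities while the jet-washed inter-tear
region and the TL stay patent. See the `thrombosis-model` vignette for the
model, units, numerical choices and known desk-scale limitations.

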