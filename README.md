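# fsuaxial

Reduced-order axial-compression analysis of bone-disc-bone spinal specimens
(functional spinal units, FSUs), for biomechanics researchers developing and
screening nucleus-augmentation interventions. The package replicates, at
desk scale and fully in silico, the analysis chain of a static compression
study of four specimen groups — intact controls (CON), bone-plug controls
(BP), trans-endplate nucleotomy (NR) and hydrogel-augmented (PEP) — where
specimen-specific finite-element models would normally stand behind the
computational arm.

## What it computes

* **Constitutive laws** (`holzapfel_params()`, `mooney_rivlin_params()`,
  `greyscale_map()`, `cauchy_stress()`): a Holzapfel-type anisotropic
  hyperelastic annulus fibrosus,

  W = c10 (Ī₁ − 3) + k1/(2 k2) Σᵢ [exp(k2 ⟨Ēᵢ⟩²) − 1] + (K/2)(ln J)²,

  with tension-only fibre families at ±20° from the hoop direction
  (c10 = 0.32 MPa, K = 2200 MPa, k1 = 2.45 MPa, k2 = 2.11); an
  incompressible Mooney-Rivlin nucleus,
  σ = 2(λ² − λ⁻¹)(c10 + c01/λ) with c10 = 0.07, c01 = 0.02 MPa; vertebral
  bone with modulus mapped linearly from image greyscale onto 10-910 MPa
  (average 409 MPa); linear-elastic PMMA (1.5 GPa).
* **A forward specimen model** (`specimen()`, `specimen_response()`,
  `disc_force()`, `bone_strain_contribution()`): annulus ring and nucleus
  core in parallel (2:1 annulus:nucleus diameter ratio), in series with two
  greyscale-mapped bone segments, loaded from a 10 N preload to 2.1 kN.
* **A seeded synthetic cohort** (`cohort_config()`, `generate_cohort()`):
  4 × 6 specimens with reported bone-length and modulus distributions, a
  hydration stiffness scatter, an NR annulus-collapse factor, and 1%
  proportional force noise for the "experimental" arm.
* **The continuous tri-linear fit** (`normalize_curve()`,
  `fit_trilinear()`): effective stress / engineering strain curves reduced
  to three effective Young's moduli (initial, transition, linear) and two
  transition strains by profiled non-linear least squares, with NRMSE (% of
  stress range) and Pearson r.
* **The statistics layer** (`compare_groups()`, `variance_f_test()`,
  `regression_r2()`, `lin_ccc()`): Shapiro-gated ANOVA / Kruskal-Wallis
  with post hoc pairwise t-tests, two-sided variance F-tests, OLS R², and
  Lin's concordance correlation coefficient
  ρc = 2 s_xy / (s_x² + s_y² + (x̄ − ȳ)²).
* **Orchestration** (`run_full()`, `run_sensitivity()`, `write_report()`):
  cohort → curves → fits → group comparison → experimental-vs-computational
  concordance → bone-rigidity sensitivity study (heterogeneous vs
  homogeneous-average vs near-rigid bone), all deterministic under one seed.

## Worked example

```r
library(fsuaxial)

s     <- specimen("demo")                       # default CON specimen
curve <- specimen_response(s, load_protocol())  # 10 N preload -> 2.1 kN
ss    <- normalize_curve(curve, area = s$geometry$disc_area,
                         height = s$geometry$disc_height)
fit   <- fit_trilinear(ss)
fit
#> Continuous tri-linear stress/strain fit (60 points)
#>   EYM (MPa): initial 4.436, transition 9.955, linear 17.61
#>   transition strains: 0.1441, 0.2489
#>   NRMSE 0.823% of stress range, Pearson r 0.99961

round(100 * bone_strain_contribution(s), 1)
#> [1] 8.7
```

The fitted moduli say the default specimen has a compliant toe region
(4.4 MPa) stiffening through a transition zone (10.0 MPa) into a linear
zone (17.6 MPa), with the two regime changes at 14% and 25% engineering
strain; the tri-linear form describes the simulated curve to within 0.9% of
the stress range. At peak load, 8.7% of the apparent axial deformation of
this specimen occurs in the vertebral bone rather than the disc — which is
why the bone cannot be treated as rigid.

The full study runs as one call and returns tidy tables
(`report$fits`, `report$group_comparison`, `report$concordance`,
`report$bone_contribution`, `report$sensitivity`):

```r
report <- run_full(cohort_config(seed = 1))
autoplot(report$cohort)
plot_group_metrics(dplyr::filter(report$fits, arm == "computational"))
```

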