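---
title: "A reduced-order model of axial compression of bone-disc-bone specimens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of axial compression of bone-disc-bone specimens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsuaxial)
```

## The problem

Preclinical screening of nucleus-augmentation biomaterials uses bone-disc-bone
specimens (functional spinal units, FSUs) compressed axially to a fixed peak
load. Four treatment groups are compared: intact controls (CON), bone-plug
controls (BP, a trans-endplate drill hole refilled with an allograft plug but
with the nucleus intact), nucleotomised specimens (NR, nucleus removed through
the endplate) and hydrogel-augmented specimens (PEP). Each measured
force-displacement curve is normalised to effective stress (force over disc
cross-sectional area) and engineering strain (displacement over disc height)
and summarised by a continuous tri-linear fit: three effective Young's moduli
(initial, transition, linear) and two transition strains. Groups are compared
statistically, and paired analyses (experimental vs computational arm;
baseline vs altered-bone models) are summarised with least-squares regression
and Lin's concordance correlation coefficient (CCC).

`fsuaxial` implements this entire analysis chain at desk scale. Since
specimen-specific finite-element models cannot be rebuilt from printed data,
the 3-D models are replaced by a reduced-order structural surrogate, and the
animal cohort by a seeded synthetic cohort generator. The statistical and
curve-fitting machinery is implemented exactly.

## Constitutive models

* **Annulus fibrosus** — anisotropic hyperelastic (Holzapfel-type):
  an isochoric neo-Hookean matrix $c_{10}(\bar I_1 - 3)$ with
  $c_{10} = 0.32$ MPa; two symmetric tension-only collagen fibre families at
  $\pm 20^\circ$ from the circumferential direction contributing
  $\tfrac{k_1}{2k_2}\left[e^{k_2 \langle\bar E\rangle^2}-1\right]$ each, with
  $k_1 = 2.45$ MPa, $k_2 = 2.11$ and
  $\bar E = \kappa(\bar I_1 - 3) + (1-3\kappa)(\bar I_4 - 1)$
  (dispersion $\kappa = 0$ by default); and a volumetric part
  $U(J) = \tfrac{K}{2}(\ln J)^2$ with $K = 2200$ MPa (the compressibility of
  water). $U$ was chosen for simplicity: any convex law with $U''(1) = K$
  would do, and this one satisfies the calibration exactly
  (`initial_bulk_modulus()`).
* **Nucleus pulposus** — incompressible Mooney-Rivlin,
  $c_{10} = 0.07$, $c_{01} = 0.02$ MPa. Under uniaxial loading with
  traction-free lateral faces the axial Cauchy stress has the closed form
  $\sigma = 2(\lambda^2 - \lambda^{-1})(c_{10} + c_{01}/\lambda)$
  (`uniaxial_stress_mr()`).
* **Vertebral bone** — linear elastic with Young's modulus mapped linearly
  from the 8-bit image greyscale, $E = 10 + \tfrac{900}{255}\,\mathrm{GS}$
  MPa, $\nu = 0.3$. The published calibration prints only the resulting
  modulus range (10-910 MPa) and volume average (409 MPa), so the default
  map spans exactly that range; both coefficients are configurable.
* **PMMA end-cap cement** — linear elastic, $E = 1.5$ GPa, $\nu = 0.3$.

Stresses are always the analytic stretch-derivatives of the strain energy,
$\sigma_i = (\lambda_i/J)\,\partial W/\partial\lambda_i$, and the test suite
verifies them against central finite differences on randomised states.

Two conventions were genuinely open and are worth flagging. First, the fibre
angle is stated relative to the sagittal plane without fixing the
lamella-plane convention; here the fibre unit vectors lie in the
circumferential-axial plane at $\pm$ `fiber_angle_deg` from the hoop
direction, exposed as a parameter. Second, because the fibres live in that
plane, the radial and circumferential directions are materially inequivalent:
only the fibre-free part of the law is symmetric under a lateral-stretch
swap, while the full law is symmetric under interchange of the two fibre
families.

## The reduced-order forward model

A specimen is a series chain: superior bone segment, disc, inferior bone
segment (plus an optional PMMA end-cap element, off by default because the
embedding depth is not known). The disc is a parallel pair of homogeneous
columns: the annulus ring (75% of the disc area) and the nucleus core (25%,
from the 2:1 annulus:nucleus diameter ratio).

At a prescribed axial stretch the annulus lateral stretch is solved so that
the mean lateral Cauchy stress vanishes (traction-free lateral surface; a
"confined" variant that imposes the isochoric lateral stretch shared with
the nucleus is available behind the `lateral` switch). The nucleus acts in
parallel as an incompressible uniaxial Mooney-Rivlin column. Axial force is
Cauchy stress times current area; for the annulus this reduces to reference
area times $\partial W/\partial\lambda_z$. Bone segments are linear springs
$\delta = F L/(E A)$ with $A$ the disc cross-section. The curve builder
inverts the disc force monotonically on a grid of force levels from the 10 N
preload to the 2.1 kN peak (60 points by default) and re-zeroes displacement
at the preload point, mirroring the experimental origin.

Group modifications: BP multiplies the superior vertebral modulus by a plug
factor (default 1); PEP replaces the nucleus parameters by hydrogel
parameters (default equal to the native nucleus, reflecting the design goal
of the gel); NR removes the nucleus and applies an annulus collapse factor.

**The collapse mechanism deserves its own paragraph.** A first formulation
scaled only the annulus stiffness coefficients. That provably cannot make a
nucleotomised specimen look softer in the *terminal* segment of a
force-terminated test: for a fibre response that grows (super-)exponentially
in strain, the tangent at a fixed peak stress is approximately
$\mathrm{d}\ln\sigma/\mathrm{d}\varepsilon \times \sigma_{\max}$, so a
multiplicative prefactor merely shifts the curve along the strain axis while
geometric hoop amplification ($\mathrm{d}\bar I_4/\mathrm{d}\varepsilon
\propto \cos^2\theta/\lambda_z^2$) restores the slope. Physically, what a
collapsing ring loses is fibre *recruitment*: bulging into the nucleotomy
void means less hoop-fibre stretch develops per axial strain. The collapse
factor therefore scales the matrix stiffness $c_{10}$, the strain-stiffening
exponent $k_2$ and a fibre-recruitment coupling that multiplies the fibre
strain measure $\bar E$ before it enters the exponential
(`fiber_coupling` in `holzapfel_params()`).

Bone-rigidity sensitivity variants (`sensitivity_variant()`):
`heterogeneous` keeps the specimen-specific moduli; `homogeneous_average`
maps both vertebrae from the cohort-average greyscale; `near_rigid` uses the
PMMA modulus (1500 MPa).

## The synthetic cohort

`cohort_config()` fixes the study conditions: four groups of six specimens.
Anchored quantities use the reported values: bone segment lengths
$\mathcal N(15.72, 1.49^2)$ mm superior and $\mathcal N(15.44, 2.27^2)$ mm
inferior; vertebral mean greyscale $\mathcal N(113.05, 15^2)$ clipped to
$[0, 255]$, whose mapped moduli average 409 MPa — the 15-greyscale spread is
a per-vertebra *volume average* spread, deliberately much narrower than the
printed per-element 10-910 MPa range. Quantities the study does not print
are stand-ins, flagged as such: disc diameter $\mathcal N(30, 1.5^2)$ mm and
height $\mathcal N(8, 0.5^2)$ mm (the study normalised per specimen but
printed no disc dimensions). A per-specimen lognormal "hydration" multiplier
(log-SD 0.1) scatters annulus and nucleus stiffness, encoding the
attribution of unexplained experimental variance to tissue hydration. NR
specimens draw their collapse factor from lognormal(log 0.5, 0.3): the
nucleotomy removes a 10-mm core from a nucleus roughly 15 mm across, so
losing about half the hoop engagement is a reasonable centre, and the wider
log-spread (0.3 > 0.1) makes NR the most variable group, as observed.
Measurement noise is proportional Gaussian on force, 1% by default; noisy
curves keep strictly increasing displacement but may jitter out of force
monotonicity exactly as load-cell readings do, while noise-free
forward-model curves are strictly monotone by construction.

Randomness is organised as per-specimen substreams drawn in a documented
block order (geometry, then materials, then noise), so enlarging the cohort
never changes earlier specimens, and a fixed seed reproduces the cohort
bit-identically.

## The tri-linear fit

The model is the continuous piecewise-linear form
$$\sigma(\varepsilon) = \sigma_0 + E_1\min(\varepsilon,\varepsilon_1)
 + E_2\,\mathrm{clamp}(\varepsilon-\varepsilon_1, 0, \varepsilon_2-\varepsilon_1)
 + E_3\max(\varepsilon-\varepsilon_2, 0),$$
with the intercept fixed at zero by default (curves are re-zeroed at the
preload; a free intercept is available). The five-parameter least-squares
problem is solved by profiling: for any breakpoint pair the three slopes are
an exact linear least-squares solve, so the outer optimisation is a 2-D
Nelder-Mead search in a smooth bounded transform
($\varepsilon_1 = \varepsilon_{\max} s_1$,
$\varepsilon_2 = \varepsilon_1 + (\varepsilon_{\max}-\varepsilon_1)s_2$,
$s_i \in (0.02, 0.98)$ via a scaled logistic) that guarantees ordered
interior breakpoints without penalties. Five deterministic starts at fixed
strain-quantile pairs guard against local minima (relative tolerance
$10^{-14}$, at most 4000 evaluations). If any two fitted slopes agree within
1% the breakpoints are unidentifiable: the fit is flagged degenerate and the
breakpoints are reported at the 33rd/66th strain percentiles with slopes
re-solved there. Goodness of fit is reported as RMSE normalised by the
observed stress range (in %) — the normalisation basis of the original
percentage RMSE is not stated, so this choice is documented here — plus the
Pearson correlation between data and fit. A brute-force grid search over
breakpoint pairs with exact inner least squares serves as an independent
optimality oracle in the tests, never as the implementation.

## Statistics

Group comparisons mirror the study's gating: Shapiro-Wilk per group at
$\alpha = 0.05$; one-way ANOVA when every group passes, otherwise
Kruskal-Wallis; post hoc pairwise t-tests (Welch) only after a significant
ANOVA, unadjusted by default because no multiplicity adjustment is reported
(a Holm flag is provided). Variance comparisons use the two-sided F-test;
paired analyses report the OLS $R^2$ and Lin's CCC,
$\rho_c = 2 s_{xy}/(s_x^2 + s_y^2 + (\bar x - \bar y)^2)$, in its original
population-moment (1/n) form with a sample-moment variant behind a flag.

## The full pipeline

```{r, eval = FALSE}
report <- run_full(cohort_config(seed = 1))
report
autoplot(report$cohort)
plot_group_metrics(report$fits[report$fits$arm == "computational", ])
```

`run_full()` generates the cohort, fits both arms (the noise-free curves
play the computational role, the noisy curves the experimental role),
compares the groups per metric, computes the experimental-vs-computational
concordance table, the CON-group bone strain contributions, and the
bone-rigidity sensitivity study (CCC of every metric between the
heterogeneous baseline and each homogeneous variant). All tables are
tibbles, every row traces to a specimen id, and the whole report is
deterministic under the configuration seed. Problem sizes throughout
(24 specimens, 60-point curves, 5 fit starts) are the package defaults and
keep a complete run in the tens of seconds on one core.

## What passing tests do and do not show

The generator emulates the *structure* of the study data — toe-then-linear
monotone loading to 2.1 kN after a 10 N preload, group sizes, bone geometry
and modulus distributions, larger NR variance — but not fluid flow,
viscoelasticity, preconditioning history, failure events or real annulus
lamellar architecture; its disc dimensions are invented defaults, not
measurements. Passing tests therefore demonstrate correctness of the
constitutive laws, the structural series/parallel mechanics, the fitting and
statistical machinery, and the qualitative replication of the study's
computational findings that survive the surrogate's simplifications: the
nucleotomy group is softer in the toe and transition regions with delayed
transition strains, bone contributes a non-negligible share of the apparent
strain, and average-homogenised bone concords far better with the
heterogeneous baseline than near-rigid bone.

One qualitative finding does not fully transfer, and deliberately so. With
every curve terminated at the same peak force, the terminal-slope argument
above compresses group differences in the *linear* effective Young's
modulus; the original study's computational arm was displacement-matched to
each experiment, so its softer nucleotomy models terminated at lower stress
and hence lower terminal slope. In this package both arms share one forward
model, so displacement-matching degenerates to the identical curve and that
mechanism is unavailable. The corresponding acceptance check is kept in its
strict form and is expected to flag this limitation rather than have the
model quietly re-tuned around it.

## Known limitations

* Each vertebra is collapsed to one effective greyscale-mapped modulus; how
  much within-vertebra heterogeneity matters cannot be judged from printed
  data.
* The disc surrogate deforms homogeneously per constituent; no 3-D stress
  fields, no endplate fluid flow, no plug contact mechanics, no rate
  effects (the originals are quasi-static elastic too).
* The incompressible nucleus column ignores the pressure-vessel interaction
  with the annulus ring, so the nucleus's share of specimen stiffness is
  modest; group effects are carried mainly by the annulus collapse
  mechanism.
* Greyscale-modulus calibration coefficients are reconstructed from the
  printed modulus range, not from the cited calibration itself.
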