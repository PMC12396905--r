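---
title: "Contact stress modelling of the dysplastic hip with hipdea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contact stress modelling of the dysplastic hip with hipdea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipdea)
```

## The model and its assumptions

`hipdea` implements discrete element analysis (DEA) of the hip: the
subchondral bone of the acetabulum and femoral head is rigid, and the
cartilage between them is a bed of independent compressive springs. One
spring is anchored on each acetabular subchondral element; its axis is
the fixed ray from the joint centre through the element centroid, and
the contact stress on the element is

$$p_i = k_i\,\delta_i,\qquad
  k_i = \frac{E\,(1-\nu)}{(1+\nu)(1-2\nu)}\,\frac{1}{h_i},$$

where $\delta_i$ is the interpenetration of the femoral cartilage outer
surface with the acetabular cartilage contact surface along the spring
ray, and $h_i$ the combined (series) thickness of the two cartilage
layers on that ray. The aggregate-modulus form is the standard
elastic-foundation stiffness for a confined, isotropic linear elastic
layer; a plain $E/h$ law can be selected via the `law` argument of
`spring_constant()`. Springs carry compression only ($\delta_i \le 0$
contributes nothing): there is no tension, no shear, no friction, and no
transverse coupling between neighbouring springs (the "barrelling" of a
compressed layer is outside the model class, as is any labrum or
ligament load sharing).

At each quasistatic load instance the femoral head is rotated by the
prescribed hip angles and translated with three degrees of freedom until
the spring reactions balance the applied joint reaction force,
$\;R(t)=F-\sum_i p_i a_i \hat u_i \to 0$. Stresses and areas are carried
on the acetabular subchondral elements; with a subchondral radius $R$
this reproduces the closed-form spring-bed solution for a congruent
ball-in-hemisphere under a polar load, $p(\gamma)=p_{\max}\cos\gamma$
with $p_{\max}=3F/(2\pi R^2)$, which the test suite and the acceptance
script verify to within 3% at a 0.7 mm mesh.

## Coordinate conventions

All processing uses a pelvis-fixed right-handed frame: +X anterior, +Y
superior, +Z lateral toward the studied hip; left hips are mirrored to
this right-hip convention. Units are mm, N, MPa, seconds and degrees
throughout, so stress emerges naturally as N/mm². The femoral pose
rotation is flexion about +Z, then abduction about +X, then internal
rotation about +Y; the composition order is a documented convention (the
angle triple alone does not fix it) and the angles involved in gait are
small enough that the choice does not drive the results.

## Cartilage generation

Two generators build the cartilage contact surfaces from subchondral
meshes:

* `shivanna_offset()` (healthy morphology): every vertex moves
  `offset` (default 1 mm) along its radial axis into the joint space —
  toward the joint centre on the acetabular side, away from it on the
  femoral side — followed by `sphericity_smooth()`: 5 Jacobi-style
  passes in which each vertex radius moves toward the mean radius of
  its 1-ring neighbours, clamped at 0.05 mm per pass. The simultaneous
  (rather than sweep-ordered) update makes the result independent of
  vertex ordering. On a perfect sphere the smoothing is the identity and
  the layer is exactly concentric with 1.000 mm thickness.
* `nishii_offset()` (dysplastic morphology, acetabular side only):
  vertices move inward by a thickness map evaluated at their spherical
  coordinates. The map is a thin-plate (biharmonic) spline over
  (polar, azimuth) with an affine polynomial part, so interpolation is
  exact at the samples and constants/linear ramps are reproduced
  exactly; evaluation is clamped below at 0.2 mm to keep thickness
  physical. The packaged 12-site default map (≈1.4 mm centrally rising
  to ≈2.6 mm at the lateral rim) is synthetic, emulating the reported
  rim-thickened pattern of dysplastic hips; real mappings are supplied
  as `data.frame(polar_deg, azimuth_deg, thickness_mm)`.

Per-element thickness is the mean radial gap over the element's
vertices in both generators, which makes the constant-map dysplastic
layer coincide exactly with the unsmoothed radial offset — a useful
cross-model identity that the tests assert to 10⁻⁹ mm. The "re-meshing"
step of the map-based generator is realized as a topology-preserving
vertex offset: element correspondence is kept so thickness bookkeeping
stays exact, at the price of slightly anisotropic elements where the map
gradient is large.

## Gait loading

A gait loading profile (GLP) is a stance-phase time series of the JRF
(as % body weight) and three hip angles. `synth_glp()` builds
double-bump profiles from three families that mirror the qualitative
contrasts between published profiles: `bergmann_like` (lowest overall
JRFs, ≈233 %BW peak, no axial rotation — the instrumented-implant
convention of setting an unreported channel to zero), `harris_like`
(≈280 %BW, the largest medially directed force share) and
`skalshoi_like` (≈320 %BW, the most vertical force direction and the
least hip extension). The defaults are the package's study conditions
and are not tuned per analysis.

`discretize_gait()` anchors seven evenly spaced quasistatic instances on
the two loading peaks: spacing $\Delta=(t_{po}-t_{hs})/4$, instance
times $t_{hs}+(k-2)\Delta$, so heel strike is instance 2 and push-off
instance 6. Times falling outside the stance interval (possible for
peaks near the edges) are clipped to the boundary and reported. The
paper-style dose metrics need an absolute time scale, which a
stance-normalized profile does not carry; the package exposes
`stance_duration` (default 0.6 s, a typical adult walking stance time)
and sets $\Delta t = \Delta \times$ `stance_duration`.

## Solver numerics

The equilibrium search is a damped Levenberg–Marquardt iteration on the
3-vector residual with a central-difference Jacobian (step 10⁻⁶ mm —
deliberately straddling the contact-set kink so marginal elements do not
destabilize the Newton direction). Convergence and divergence follow the
modelled method exactly: equilibrium at residual < 10⁻⁶ N; divergence
after 400 iterations or when the proposed step falls below 10⁻⁶ mm
without the residual criterion being met. Because the residual is
near-linear in the translation, the final Newton step typically lands on
equilibrium in one shot; the residual check therefore precedes the
small-step check. Penetrations are exact ray–sphere overlaps along the
fixed spring axes; overlaps below 10⁻¹² mm (coordinate roundoff) are
treated as separation. When the femoral layer is an exact sphere with
uniform thickness — the default synthetic geometry — the femoral radius
along every ray is a constant and the solve is closed-form fast; with
radial noise the femoral radial field is looked up once per instance
(nearest sampled direction in the femur body frame), not per iteration,
since equilibrium translations are three orders of magnitude smaller
than the head radius.

Sequences are solved warm-started (each instance initialized at the
previous equilibrium, the first at zero), mimicking quasistatic
continuity; a regression test checks cold starts land on the same
equilibria. A sequence is all-or-nothing: if any of the seven instances
diverges the whole sequence is excluded from the metrics, so metric
definitions (means and sums over exactly seven instances) are never
silently altered.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` stands in for a clinical imaging cohort. Each hip is
a parametric geometry: a spherical femoral head (radius ≈24 mm, optional
radial noise), a concentric acetabular cup whose rim polar angle varies
with azimuth (piecewise-linear periodic interpolation between lateral /
anterior / inferior / posterior anchors), a 10° medial trim whose
superior edge serves as the medial sourcil proxy, and a cup axis with
physiologic inclination/anteversion variability. Covariates follow the
study population they emulate: age 34.6 ± 6.4 yr, weight 72.5 ± 14.2 kg,
height 1.69 ± 0.08 m, 16/22 female, truncated at physiologic bounds; an
optional bilateral flag duplicates one subject with independent
geometry, giving 23 hips from 22 subjects and exercising the
uneven-sample bookkeeping. Pre-operative LCEA/ACEA targets are drawn
from dysplastic ranges (17 ± 7.4°, 21.4 ± 12°) and met exactly by
root-finding on the coverage anchors; the PAO is a rigid cup rotation
about the head centre solved to reach drawn healthy-range targets
(28.6 ± 5.2°, 31.8 ± 9.5°) plus 2° correction noise.

The radiographic measures are geometric proxies computed by orthographic
projection in neutral pelvic alignment: LCEA and ACEA from the superior
frontal-plane and anterior sagittal-plane rim crossings, AI from the
medial sourcil point to the LCEA rim point, AAA from the axial
anterior–posterior rim chord, FHEI from the frontal head width lateral
to the LCEA rim point. They are stated conventions, not claims of
equivalence with manual radiographic reads: real measurements carry
magnification, pelvic tilt and landmark ambiguity that the generator
deliberately omits. Likewise the generator does not emulate aspherical
(cam-type) heads beyond radial noise, acetabular version deformities
beyond the coverage anchors, real bone roughness, or patient-specific
cartilage. Passing tests therefore demonstrate that the pipeline's
machinery recovers built-in coverage–stress couplings under controlled
conditions — not that it reproduces any clinical cohort's values.

## Study statistics

The factorial study crosses 2 cartilage models × 3 GLPs × pre/post over
the cohort (84 instance solves per subject; 6 scenarios). Statistics
mirror standard practice for this design: paired t tests for pre/post
changes (α = 0.05, two-sided, no multiplicity correction — a reporting
convention, not a recommendation); a 240-cell weighted Pearson grid
(8 metrics × 5 measures × 6 scenarios) pooling pre and post observations
with group weights equalized (each pre pair weighs $W/n_{pre}$, each
post pair $W/n_{post}$) so uneven divergence counts cannot skew the
pooled correlation, with significance via a t transform at the Kish
effective sample size (the weighted-p procedure is otherwise
underdetermined); and forward stepwise regression with F-to-enter 3.84
and F-to-remove 2.71, collinear candidates barred from entry. Sex enters
regressions coded 0/1. Omnibus repeated-measures MANOVA/ANOVA machinery
is deliberately out of scope: the directional conclusions are carried by
the paired tests and the correlation/regression sensitivity analysis.

## Problem sizes and reproducibility

The packaged study conditions are: cohort n = 22 subjects (23 hips),
1.5 mm target element size for cohort meshes (≈2,500–4,500 acetabular
elements per hip), 0.7 mm for the analytic-oracle verification
(≈18,000 elements), fixed seeds for every random draw. A full cohort
study (276 sequences, 1,932 instance solves) runs in about a minute on
one CPU; the acceptance script repeats design counts, the analytic
oracle, the cohort study, the correlation sign pattern and the stepwise
recovery from scratch from a single seed.

## Known limitations

* Rigid bone, compression-only independent springs: no load sharing by
  labrum or round ligament, no transverse stress redistribution, so
  local stress peaks are sharper than a finite element model would
  predict.
* Spring axes are fixed cup-centre rays; for the near-concentric
  geometries studied the axis error is second order, but the model is
  not suited to grossly incongruent joints.
* The stance duration behind the MPa·s dose metrics is a configurable
  constant, not subject-specific gait timing.
* Synthetic thickness maps and loading profiles emulate published
  qualitative patterns; none of the packaged defaults are measured
  data.
* Radiographic proxies are 3D geometric conventions; absolute values
  (AI and FHEI especially) are offset relative to clinical reads, so
  analyses should rely on within-cohort variation, which is what the
  correlation and regression machinery uses.
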