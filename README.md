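# hipdea

Discrete element analysis (DEA) of hip joint contact stress across the
stance phase of gait, built for studying developmental dysplasia of the
hip (DDH) and its surgical correction by periacetabular osteotomy (PAO).
The package targets biomechanics researchers who want to relate
radiographic measures of acetabular coverage (LCEA, AI, ACEA, AAA, FHEI)
to osteoarthritis-predictive contact stress metrics under controlled,
reproducible simulation conditions.

## The model

DEA (the bed-of-springs method) treats the subchondral bone as rigid and
the cartilage as a bed of independent compressive springs. Each spring
sits on an acetabular subchondral element of area *aᵢ*, acts along the
radial axis through the element centroid, and responds only to
interpenetration δᵢ of the two cartilage contact surfaces:

    pᵢ = k δᵢ,   k = E (1 − ν) / ((1 + ν)(1 − 2ν)) / h

with the confined-compression (aggregate) modulus of an isotropic linear
elastic cartilage (defaults E = 12 MPa, ν = 0.43) and h the combined
acetabular + femoral cartilage thickness in series along the spring ray.
The femoral head has three translational degrees of freedom; its hip
angles (flexion, abduction, internal rotation) are prescribed per load
instance. A Levenberg–Marquardt search finds the translation balancing
the applied joint reaction force (JRF) against the spring reactions:
equilibrium when ‖F − Σ pᵢ aᵢ ûᵢ‖ < 10⁻⁶ N, divergence (subluxation)
after 400 iterations or when the displacement step falls below 10⁻⁶ mm.

Around this core the package provides:

* **Cartilage generation** from subchondral meshes: a radial 1 mm offset
  with sphericity smoothing (5 passes, 0.05 mm step clamp) for healthy
  cartilage, or a biharmonic-spline thickness map (thicker at the
  acetabular rim) for dysplastic cartilage.
* **Gait loading**: double-bump stance profiles (three synthetic
  families mirroring instrumented-implant and dysplastic gait data),
  discretized into 7 evenly spaced quasistatic instances with heel
  strike and push-off anchored at instances 2 and 6.
* **Eight stress metrics** per gait sequence: absolute/average peak
  stress, peak stress–time dose, average contact area, average stress,
  supra-threshold area (> 9.5 MPa), Maxian overdose (> 6 MPa), and the
  supra-threshold elevated contact area (dose > 5.5 MPa·s over area ever
  > 4 MPa).
* **A synthetic cohort generator**: parametric dysplastic hips spanning
  configurable LCEA/ACEA ranges, PAO as a rigid cup reorientation with
  correction noise, subject covariates, and the five radiographic
  measures computed from 3D geometry by orthographic projection.
* **Study statistics**: the 2 × 3 factorial scenario grid (84 instance
  solves per subject), paired t tests, weighted Pearson correlation
  grids (240 cells) with equalized pre/post group weights, and forward
  stepwise regression (F-in 3.84, F-out 2.71).

## Worked example

```r
library(hipdea)

geom <- hip_geometry(head_radius = 23, clearance = 2,
                     target_element_size = 1.5)
geom <- calibrate_coverage(geom, target_lcea = 17, target_acea = 21)
geom
#> hip_geometry: head R 23.0 mm, cup R 25.0 mm | LCEA 17.0, AI 9.4, ACEA 21.0, AAA 23.7, FHEI 34.1

model <- build_hip_model(geom, cartilage = "nishii")
model
#> dea_model: 2660 springs, acetabular area 2747 mm^2, femur spherical (fast path)

instances <- discretize_gait(synth_glp("harris_like"), body_weight = 72.5)
instances
#> load_instances 'harris_like': 7 instances, dt 0.0840 s, peak force 1991 N

seq <- solve_sequence(model, instances)
seq
#> gait_stress_sequence: 7 instances, dt 0.0840 s, A 2747 mm^2, peak 13.280 MPa

str(compute_stress_metrics(seq))
#> List of 8
#>  $ absolute_peak_stress       : num 13.3
#>  $ average_peak_stress        : num 11.2
#>  $ peak_stress_time_dose      : num 6.58
#>  $ average_contact_area       : num 25.3
#>  $ average_stress             : num 3.46
#>  $ average_suprathreshold_area: num 0.953
#>  $ maxian_overdose            : num 4.67
#>  $ ste_contact_area           : num 5.77
```

The hip here is a calibrated dysplastic geometry (LCEA 17°, ACEA 21°)
loaded with the dysplastic-gait-like profile: roughly a quarter of the
acetabulum carries load on average, mean contact stress is ≈ 3.5 MPa,
and a small rim region exceeds the 9.5 MPa damage threshold. A full
cohort study is one call:

```r
cohort <- generate_cohort(22, seed = 1)          # 23 hips, one bilateral
study  <- run_study(cohort)                      # 6 scenarios x pre/post
summarize_treatment_effects(study)$aggregate     # post-PAO changes
correlation_grid(study)                          # 240-cell grid
```

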