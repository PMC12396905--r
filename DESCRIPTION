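Package: hipdea
Title: Discrete Element Analysis of Hip Joint Contact Stress in Dysplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bed-of-springs (discrete element) contact modelling of the
    dysplastic hip across the stance phase of gait. Builds cartilage layers
    from subchondral surface meshes using a radial-offset model with
    sphericity smoothing or a biharmonic-spline thickness map, discretizes
    gait loading profiles into seven quasistatic load instances anchored on
    the heel-strike and push-off peaks, solves the quasistatic contact
    equilibrium of the femoral head in the acetabulum, and computes eight
    osteoarthritis-predictive contact stress metrics. Includes a parametric
    synthetic cohort generator for dysplastic hips with simulated
    periacetabular osteotomy, radiographic coverage measures (LCEA, AI,
    ACEA, AAA, FHEI), and study-level statistics: paired tests, weighted
    correlation grids, and forward stepwise regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, tools, utils
Suggests: testthat (>= 3.0.0), minpack.lm, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
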