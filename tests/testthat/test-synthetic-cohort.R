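test_that("femoral head generator respects radius, element size and seeding", {
  g <- hip_geometry(head_radius = 25, clearance = 0,
                    target_element_size = 0.7)
  head <- generate_femoral_head(g)
  v <- head$surface$vertices
  r <- sqrt(rowSums(v^2))
  expect_lt(max(abs(r - 25)), 1e-9)
  f <- head$surface$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), ]
  mean_edge <- mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
  expect_gte(mean_edge, 0.56)
  expect_lte(mean_edge, 0.84)
  # seeded noise is reproducible and bounded
  gn <- hip_geometry(head_radius = 25, head_noise = 0.1,
                     target_element_size = 1.5)
  h1 <- generate_femoral_head(gn, seed = 42L)
  h2 <- generate_femoral_head(gn, seed = 42L)
  h3 <- generate_femoral_head(gn, seed = 43L)
  expect_identical(h1$surface$vertices, h2$surface$vertices)
  expect_false(identical(h1$surface$vertices, h3$surface$vertices))
  rn <- sqrt(rowSums(h1$surface$vertices^2))
  expect_lte(max(abs(rn - 25)), 0.1 + 1e-12)
})

test_that("hemispherical cup area matches the closed form within 2%", {
  g <- hip_geometry(head_radius = 25, clearance = 0, cup_axis = c(0, 0, 1),
                    coverage = 90, medial_trim = 1,
                    target_element_size = 0.7)
  cup <- generate_acetabulum(g)
  area <- sum(cup$surface$element_area)
  expect_lt(abs(area - 2 * pi * 625) / (2 * pi * 625), 0.02)
})

test_that("near-zero coverage yields a near-empty cup", {
  g <- hip_geometry(coverage = 6, medial_trim = 2, target_element_size = 1)
  cup <- generate_acetabulum(g)
  # tiny annular cap: area is a small fraction of the hemisphere
  expect_lt(sum(cup$surface$element_area), 0.02 * 2 * pi * g$cup_radius^2)
  expect_error(rim_coverage(-5), "within")
})

test_that("rim depth varies monotonically between coverage anchors", {
  cov <- rim_coverage(c(lateral = 55, anterior = 70))
  az <- seq(0, 90, by = 5)
  th <- cov(az)
  expect_equal(th[1L], 55)
  expect_equal(th[length(th)], 70)
  expect_true(all(diff(th) >= 0))
})

test_that("PAO is a rigid reorientation: identity, inverse, coverage gain", {
  g <- calibrate_coverage(hip_geometry(), 17, 21)
  m0 <- radiographic_measures_params(g)
  ident <- simulate_pao(g, c(0, 0, 0))
  expect_equal(radiographic_measures_params(ident), m0, tolerance = 1e-12)
  # rotation then inverse rotation restores the frame
  R <- hipdea:::.rot_z(9) %*% hipdea:::.rot_y(-4) %*% hipdea:::.rot_x(15)
  back <- simulate_pao(simulate_pao(g, R), t(R))
  expect_lt(max(abs(back$cup_frame$axes - g$cup_frame$axes)), 1e-9)
  # lateral-coverage-increasing rotation raises LCEA
  m15 <- radiographic_measures_params(simulate_pao(g, c(15, 0, 0)))
  expect_gt(m15$LCEA, m0$LCEA)
  expect_error(simulate_pao(g, c(50, 0, 0)), "45")
})

test_that("radiographic measures: hand geometry on canonical cups", {
  # hemispherical cup opening purely lateral: rim in the frontal plane
  g <- hip_geometry(head_radius = 25, clearance = 0, cup_axis = c(0, 0, 1),
                    coverage = 90, medial_trim = 5, target_element_size = 1)
  m <- radiographic_measures_params(g)
  expect_equal(m$LCEA, 0, tolerance = 0.5)
  expect_equal(m$AAA, 0, tolerance = 0.5)
  expect_equal(m$FHEI, 50, tolerance = 1)  # rim at the equator: half width uncovered
  # cup wrapped far over a small head: no lateral extrusion
  g2 <- hip_geometry(head_radius = 20, clearance = 7,
                     cup_axis = c(0, -sqrt(0.5), sqrt(0.5)),
                     coverage = 118, medial_trim = 5,
                     target_element_size = 1)
  m2 <- radiographic_measures_params(g2)
  expect_equal(m2$FHEI, 0)
})

test_that("deepening lateral coverage raises LCEA and lowers AI and FHEI", {
  lcea <- ai <- fhei <- numeric(0)
  for (lat in seq(70, 110, by = 10)) {
    g <- hip_geometry(coverage = c(lateral = lat, anterior = 95,
                                   inferior = 95, posterior = 92))
    m <- radiographic_measures_params(g)
    lcea <- c(lcea, m$LCEA); ai <- c(ai, m$AI); fhei <- c(fhei, m$FHEI)
  }
  expect_true(all(diff(lcea) > 0))
  expect_true(all(diff(ai) < 0))
  expect_true(all(diff(fhei) < 0))
})

test_that("mesh-derived measures agree with the parametric ones within 2 degrees", {
  g <- calibrate_coverage(hip_geometry(target_element_size = 0.7), 15, 22)
  cup <- generate_acetabulum(g)
  mm <- radiographic_measures(cup$surface, g$center, g$head_radius)
  mp <- radiographic_measures_params(g)
  for (k in c("LCEA", "AI", "ACEA", "AAA")) {
    expect_lt(abs(mm[[k]] - mp[[k]]), 2)
  }
  expect_lt(abs(mm$FHEI - mp$FHEI), 2)
})

test_that("cohort generation is reproducible and matches configured targets", {
  c1 <- generate_cohort(5, seed = 9, config = cohort_config(bilateral = FALSE))
  c2 <- generate_cohort(5, seed = 9, config = cohort_config(bilateral = FALSE))
  expect_equal(length(c1), 5L)
  expect_identical(cohort_manifest(c1), cohort_manifest(c2))
  # bilateral flag adds a 23rd hip for n = 22 with a reused subject
  c3 <- generate_cohort(3, seed = 2, config = cohort_config(bilateral = TRUE))
  expect_equal(length(c3), 4L)
  expect_equal(c3[[4L]]$subject_id, c3[[1L]]$subject_id)
  expect_false(isTRUE(all.equal(c3[[4L]]$pre_measures, c3[[1L]]$pre_measures)))
})

test_that("zero-variance covariate config yields identical covariates", {
  cfg <- cohort_config(age_sd = 0, weight_sd = 0, height_sd = 0,
                       head_radius_sd = 0, female_prob = 1,
                       bilateral = FALSE)
  coh <- generate_cohort(4, seed = 1, config = cfg)
  man <- cohort_manifest(coh)
  expect_true(all(man$age == man$age[1L]))
  expect_true(all(man$weight_kg == 72.5))
  expect_true(all(man$height_m == 1.69))
  expect_true(all(man$sex == "F"))
})

test_that("pre-op LCEA sample mean approaches its configured target", {
  cfg <- cohort_config(bilateral = FALSE)
  coh <- generate_cohort(60, seed = 31, config = cfg)
  man <- cohort_manifest(coh)
  se <- stats::sd(man$LCEA_pre) / sqrt(nrow(man))
  # truncation at [0, 28] pulls the realized mean slightly below 17
  trunc_mean <- {
    a <- (cfg$pre_lcea_range[1] - cfg$pre_lcea_mean) / cfg$pre_lcea_sd
    b <- (cfg$pre_lcea_range[2] - cfg$pre_lcea_mean) / cfg$pre_lcea_sd
    cfg$pre_lcea_mean + cfg$pre_lcea_sd *
      (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
  }
  expect_lt(abs(mean(man$LCEA_pre) - trunc_mean), 3 * se)
})

test_that("PAO improves all coverage measures on average (sign pattern)", {
  coh <- generate_cohort(12, seed = 5, config = cohort_config(bilateral = FALSE))
  man <- cohort_manifest(coh)
  expect_gt(mean(man$LCEA_post - man$LCEA_pre), 0)
  expect_gt(mean(man$ACEA_post - man$ACEA_pre), 0)
  expect_lt(mean(man$AI_post - man$AI_pre), 0)
  expect_lt(mean(man$FHEI_post - man$FHEI_pre), 0)
})

test_that("cohort export writes PLY meshes and a readable manifest", {
  dir <- tempfile("cohort")
  coh <- generate_cohort(1, seed = 1, config = cohort_config(bilateral = FALSE))
  path <- write_cohort(coh, dir)
  man <- utils::read.csv(path)
  expect_equal(nrow(man), 1L)
  mesh <- read_surface(file.path(dir, "H01_pre_acetabulum.ply"))
  expect_s3_class(mesh, "tri_surface")
  expect_gt(sum(mesh$element_area), 0)
  unlink(dir, recursive = TRUE)
})
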