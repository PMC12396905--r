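test_that("spring constant follows the confined-compression formula", {
  mat <- material_params(12, 0.43)
  agg <- 12 * (1 - 0.43) / ((1 + 0.43) * (1 - 2 * 0.43))
  expect_equal(spring_constant(mat, 2), agg / 2, tolerance = 1e-12)
  expect_equal(spring_constant(mat, 2), 17.083, tolerance = 1e-4)
  # nu = 0 reduces to E; doubling h halves k; simple law is E/h
  expect_equal(spring_constant(material_params(12, 1e-12), 1), 12,
               tolerance = 1e-9)
  expect_equal(spring_constant(mat, 4), spring_constant(mat, 2) / 2)
  expect_equal(spring_constant(mat, 2, law = "simple"), 6)
  expect_error(material_params(12, 0.5), "0.5")
  expect_error(spring_constant(mat, 0), "> 0")
})

test_that("femur posing: identities and the flexion axis convention", {
  s <- icosphere(10, 2)
  fr <- spherical_frame(c(0, 0, 0))
  expect_equal(pose_femur(s, fr)$vertices, s$vertices, tolerance = 1e-14)
  t1 <- pose_femur(s, fr, translation = c(1, -2, 0.5))
  t2 <- pose_femur(t1, fr, translation = -c(1, -2, 0.5))
  expect_lt(max(abs(t2$vertices - s$vertices)), 1e-12)
  # 90 degrees flexion (about +Z) maps an anterior point to superior
  p <- rbind(c(1, 0, 0), c(2, 0, 0), c(1, 1, 0))
  sp <- tri_surface(p * 10, rbind(c(1, 2, 3)))
  posed <- pose_femur(sp, fr, angles = c(90, 0, 0))
  expect_lt(max(abs(posed$vertices[1, ] - c(0, 10, 0))), 1e-9)
})

test_that("penetrations: just-touching, displaced, and separated spheres", {
  m <- oracle_model(element_size = 1.5)
  expect_true(m$spherical_femur)
  d0 <- penetrations(m, c(0, 0, 0))
  expect_lt(max(d0), 1e-9)  # concentric 24 mm surfaces just touch
  # 0.1 mm toward the cup pole (deep axis -Z): peak at the pole,
  # decaying as cos(polar angle) within 2%
  d1 <- penetrations(m, c(0, 0, -0.1))
  expect_equal(max(d1), 0.1, tolerance = 2e-3)
  pol <- radial_decomposition(m$acet_layer$subchondral$element_centroid,
                              m$frame)$polar
  active <- d1 > 1e-6
  expect_lt(max(abs(d1[active] - 0.1 * cos(pol[active] * pi / 180))), 0.002)
  # displaced away from the cup: no contact at all
  d2 <- penetrations(m, c(0, 0, 5))
  expect_true(all(d2 == 0))
})

test_that("residual force vanishes without load and matches the spring sum", {
  m <- oracle_model(element_size = 1.5)
  expect_equal(residual_force(m, c(0, 0, 0), c(0, 0, 0)),
               c(0, 0, 0), tolerance = 1e-9)
  # at the analytic displacement d = 3F/(2 pi R^2 k), the residual of a
  # 1000 N polar load is below 1% of F
  k <- spring_constant(m$mat, 2)
  d <- 3 * 1000 / (2 * pi * 25^2 * k)
  r <- residual_force(m, c(0, 0, -d), c(0, 0, -1000))
  expect_lt(sqrt(sum(r^2)), 0.01 * 1000)
  # reaction opposes small displacements into the cup interior
  r2 <- residual_force(m, c(0, 0, -0.05), c(0, 0, 0))
  expect_gt(r2[3L], 0)  # springs push back along +Z against -Z motion
})

test_that("congruent hemisphere matches the closed-form spring-bed solution", {
  m <- oracle_model(element_size = 0.7)
  out <- solve_instance(m, c(0, 0, -1000))
  expect_s3_class(out, "stress_field")
  expect_lt(out$residual, 1e-6)
  p_max <- 3 * 1000 / (2 * pi * 625)
  p_mean <- 3 * 1000 / (4 * pi * 625)
  expect_lt(abs(max(out$element_stress) - p_max) / p_max, 0.03)
  act <- out$element_stress > 0
  mean_st <- sum(out$element_stress[act] * out$element_area[act]) /
    sum(out$element_area[act])
  expect_lt(abs(mean_st - p_mean) / p_mean, 0.03)
  expect_true(all(out$element_stress >= 0))
  # error shrinks under mesh refinement
  m_coarse <- oracle_model(element_size = 1.5)
  out_c <- solve_instance(m_coarse, c(0, 0, -1000))
  err_c <- abs(max(out_c$element_stress) - p_max) / p_max
  err_f <- abs(max(out$element_stress) - p_max) / p_max
  expect_lt(err_f, err_c)
})

test_that("stresses scale linearly with load on the full-contact set", {
  # penetration is the exact ray-sphere overlap, so per-element
  # proportionality holds to first order in the displacement, with a
  # quadratic geometric correction confined to the rim: the interior is
  # proportional tightly, and the worst-case deviation shrinks with the
  # load (linearization property)
  m <- oracle_model(element_size = 1.5)
  o1 <- solve_instance(m, c(0, 0, -500))
  o2 <- solve_instance(m, c(0, 0, -1000))
  expect_equal(o2$head_translation[3L] / o1$head_translation[3L], 2,
               tolerance = 1e-3)
  interior <- o1$element_stress > 0.2 * max(o1$element_stress)
  ratio <- o2$element_stress[interior] / o1$element_stress[interior]
  expect_lt(max(abs(ratio - 2)), 5e-3)
  o05 <- solve_instance(m, c(0, 0, -250))
  act_s <- o05$element_stress > 0.2 * max(o05$element_stress)
  ratio_s <- o1$element_stress[act_s] / o05$element_stress[act_s]
  expect_lt(max(abs(ratio_s - 2)), max(abs(ratio - 2)))
})

test_that("zero load converges trivially with zero stress", {
  m <- oracle_model(element_size = 2)
  out <- solve_instance(m, c(0, 0, 0))
  expect_s3_class(out, "stress_field")
  expect_true(all(out$element_stress == 0))
  expect_equal(out$iterations, 0L)
  expect_error(solve_instance(m, c(NA, 0, 0)), "finite")
})

test_that("rigid rotation of model and load preserves stress magnitudes", {
  R <- hipdea:::.rot_y(35) %*% hipdea:::.rot_x(-20)
  build <- function(rot) {
    ax <- as.numeric(rot %*% c(0, 0, 1))
    g <- hip_geometry(head_radius = 23, clearance = 2, cup_axis = ax,
                      coverage = 90, medial_trim = 2,
                      target_element_size = 1.5)
    cup <- generate_acetabulum(g)
    head <- generate_femoral_head(g)
    dea_model(shivanna_offset(cup$surface, cup$frame, side = "acetabular"),
              shivanna_offset(head$surface, head$frame, side = "femoral"),
              cup$frame)
  }
  m0 <- build(diag(3))
  m1 <- build(R)
  F0 <- c(0, 0, -1000)
  o0 <- solve_instance(m0, F0)
  o1 <- solve_instance(m1, as.numeric(R %*% F0))
  expect_s3_class(o0, "stress_field"); expect_s3_class(o1, "stress_field")
  expect_lt(abs(max(o1$element_stress) - max(o0$element_stress)), 1e-6)
  expect_lt(abs(sum(o1$element_stress * o1$element_area) -
                  sum(o0$element_stress * o0$element_area)), 1e-3)
})

test_that("shallow 25-degree cup under lateral load diverges (subluxation)", {
  g <- hip_geometry(head_radius = 23, clearance = 2, cup_axis = c(0, 0, 1),
                    coverage = 25, medial_trim = 2,
                    target_element_size = 1.5)
  cup <- generate_acetabulum(g)
  head <- generate_femoral_head(g)
  m <- dea_model(shivanna_offset(cup$surface, cup$frame, side = "acetabular"),
                 shivanna_offset(head$surface, head$frame, side = "femoral"),
                 cup$frame)
  out <- solve_instance(m, c(0, 1000, 0))  # strongly off-axis: slides out
  expect_s3_class(out, "dea_divergence")
  expect_true(out$reason %in% c("max_iterations", "min_step"))
})

test_that("independent optimizer reaches the same equilibrium", {
  skip_if_not_installed("minpack.lm")
  m <- oracle_model(element_size = 1.5)
  force <- c(80, -150, -950)
  mine <- solve_instance(m, force)
  expect_s3_class(mine, "stress_field")
  ref <- minpack.lm::nls.lm(
    par = c(0, 0, 0),
    fn = function(t) residual_force(m, t, force),
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  expect_lt(max(abs(ref$par - mine$head_translation)), 1e-6)
})

test_that("sequence solving is all-or-nothing with warm starts", {
  m <- oracle_model(element_size = 1.5)
  glp <- synth_glp("bergmann_like")
  li <- discretize_gait(glp, 72.5)
  # forces in this frame press into the cup (deep axis -Z): remap the
  # synthetic profile's superior-dominant force to the cup axis
  li$force <- cbind(0.2 * li$force[, 1L], 0, -sqrt(rowSums(li$force^2)))
  seqr <- solve_sequence(m, li)
  expect_s3_class(seqr, "gait_stress_sequence")
  expect_equal(seqr$t, 7L)
  expect_equal(seqr$dt, li$dt)
  expect_equal(seqr$total_area, sum(m$area))
  # warm vs cold starts agree
  cold <- lapply(1:7, function(j)
    solve_instance(m, li$force[j, ], li$angles[j, ]))
  for (j in 1:7) {
    expect_lt(max(abs(cold[[j]]$element_stress -
                        seqr$fields[[j]]$element_stress)), 1e-4)
  }
  # a diverging instance poisons the whole sequence
  li_bad <- li
  li_bad$force[4L, ] <- c(0, 5000, 2000)  # pulls the head out of the cup
  out <- solve_sequence(m, li_bad)
  expect_s3_class(out, "sequence_divergence")
  expect_true(4L %in% out$failed)
})

test_that("force balance at convergence meets the residual tolerance", {
  m <- oracle_model(element_size = 1.5)
  for (force in list(c(0, 0, -800), c(100, -50, -900), c(-60, 40, -500))) {
    out <- solve_instance(m, force)
    expect_s3_class(out, "stress_field")
    r <- residual_force(m, out$head_translation, force)
    expect_lt(sqrt(sum(r^2)), 1e-6)
    expect_true(all(out$element_stress >= 0))
  }
})
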