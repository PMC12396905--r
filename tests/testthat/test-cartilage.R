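test_that("radial offset on a perfect sphere is an exact concentric sphere", {
  g <- hip_geometry(head_radius = 23, clearance = 2, cup_axis = c(0, 0, 1),
                    coverage = 90, medial_trim = 3, target_element_size = 1.5)
  cup <- generate_acetabulum(g)
  layer <- shivanna_offset(cup$surface, cup$frame, shivanna_params(),
                           "acetabular")
  r <- sqrt(rowSums(layer$contact$vertices^2))
  expect_lt(max(abs(r - 24)), 1e-9)          # cup radius 25 - 1 mm offset
  expect_lt(max(abs(layer$thickness - 1)), 1e-9)
  # femoral side offsets outward
  head <- generate_femoral_head(g)
  fl <- shivanna_offset(head$surface, head$frame, shivanna_params(),
                        "femoral")
  rf <- sqrt(rowSums(fl$contact$vertices^2))
  expect_lt(max(abs(rf - 24)), 1e-9)         # head radius 23 + 1 mm offset
  expect_lt(max(abs(fl$thickness - 1)), 1e-9)
})

test_that("zero smoothing iterations give a pure radial offset", {
  set.seed(8)
  s <- icosphere(20, 2)
  s$vertices <- s$vertices * (1 + 0.01 * stats::runif(nrow(s$vertices)))
  s <- hipdea:::.refresh_elements(s)
  fr <- spherical_frame(c(0, 0, 0))
  layer <- shivanna_offset(s, fr, shivanna_params(smoothing_iterations = 0),
                           "acetabular")
  r_sub <- sqrt(rowSums(s$vertices^2))
  r_con <- sqrt(rowSums(layer$contact$vertices^2))
  expect_lt(max(abs(r_sub - r_con - 1)), 1e-12)
})

test_that("smoothing: uniform radii are a fixed point; clamp follows the update rule", {
  fr <- spherical_frame(c(0, 0, 0))
  s <- icosphere(10, 2)
  sm <- sphericity_smooth(s, fr, 5, 0.05)
  expect_lt(max(abs(sm$vertices - s$vertices)), 1e-12)
  # one vertex pushed 1 mm out: first iteration moves it back exactly
  # by the clamp, neighbours move up by their (unclamped) share
  s2 <- s
  u1 <- s2$vertices[1, ] / sqrt(sum(s2$vertices[1, ]^2))
  s2$vertices[1, ] <- u1 * 11
  s2 <- hipdea:::.refresh_elements(s2)
  sm1 <- sphericity_smooth(s2, fr, 1, 0.05)
  expect_equal(sqrt(sum(sm1$vertices[1, ]^2)), 11 - 0.05, tolerance = 1e-12)
  nb <- s$vertex_adjacency[[1L]]
  deg_nb <- vapply(s$vertex_adjacency[nb], length, 0L)
  expect_equal(sqrt(rowSums(sm1$vertices[nb, , drop = FALSE]^2)),
               10 + pmin(0.05, 1 / deg_nb), tolerance = 1e-12)
})

test_that("smoothing contracts: radius variance is non-increasing with bounded steps", {
  set.seed(21)
  fr <- spherical_frame(c(0, 0, 0))
  for (rep in 1:5) {
    s <- icosphere(15, 2)
    s$vertices <- s$vertices * (1 + 0.03 * stats::rnorm(nrow(s$vertices)))
    s <- hipdea:::.refresh_elements(s)
    prev <- s
    v_prev <- stats::var(sqrt(rowSums(prev$vertices^2)))
    for (it in 1:5) {
      cur <- sphericity_smooth(prev, fr, 1, 0.05)
      move <- abs(sqrt(rowSums(cur$vertices^2)) - sqrt(rowSums(prev$vertices^2)))
      expect_lte(max(move), 0.05 + 1e-12)
      v_cur <- stats::var(sqrt(rowSums(cur$vertices^2)))
      expect_lte(v_cur, v_prev + 1e-12)
      prev <- cur; v_prev <- v_cur
    }
  }
})

test_that("perturbed sphere: peak deviation strictly decreases over the 5 passes", {
  fr <- spherical_frame(c(0, 0, 0))
  s <- icosphere(25, 3)
  u1 <- s$vertices[7, ] / 25
  s$vertices[7, ] <- u1 * 25.2
  s <- hipdea:::.refresh_elements(s)
  dev <- function(x) max(abs(sqrt(rowSums(x$vertices^2)) - 25))
  cur <- s
  devs <- dev(cur)
  for (it in 1:5) {
    cur <- sphericity_smooth(cur, fr, 1, 0.05)
    devs <- c(devs, dev(cur))
  }
  expect_true(all(diff(devs) < 0))
})

test_that("thickness map: exact interpolation, constants, linear ramps", {
  # constants are reproduced everywhere
  const <- fit_thickness_map(data.frame(
    polar_deg = c(10, 50, 90, 50), azimuth_deg = c(0, 90, 180, 270),
    thickness_mm = 1.5))
  q <- expand.grid(p = seq(5, 100, by = 13), a = seq(-170, 170, by = 37))
  expect_lt(max(abs(evaluate_thickness(const, q$p, q$a) - 1.5)), 1e-9)
  # exact at the samples
  map <- default_thickness_map()
  s <- map$samples
  expect_lt(max(abs(evaluate_thickness(map, s$polar_deg, s$azimuth_deg) -
                      s$thickness_mm)), 1e-6)
  # linear ramp: midpoint within 5% of the linear value
  ramp <- fit_thickness_map(data.frame(
    polar_deg = c(0, 100, 0, 100, 50), azimuth_deg = c(0, 0, 80, 80, 40),
    thickness_mm = c(1, 3, 1, 3, 2)))
  mid <- evaluate_thickness(ramp, 50, 20)
  expect_lt(abs(mid - 2) / 2, 0.05)
  # validation
  expect_error(fit_thickness_map(data.frame(
    polar_deg = c(10, 10, 50), azimuth_deg = c(0, 0, 90),
    thickness_mm = c(1, 2, 1))), "duplicate")
  expect_error(fit_thickness_map(data.frame(
    polar_deg = c(10, 20, 30), azimuth_deg = c(0, 0, 0),
    thickness_mm = c(1, 2, 1))), "collinear")
  expect_error(fit_thickness_map(data.frame(
    polar_deg = c(10, 50, 90), azimuth_deg = c(0, 90, 180),
    thickness_mm = c(1, -2, 1))), "positive")
})

test_that("constant-map offset equals unsmoothed radial offset element-wise", {
  g <- calibrate_coverage(hip_geometry(target_element_size = 1.5), 20, 25)
  cup <- generate_acetabulum(g)
  const <- fit_thickness_map(data.frame(
    polar_deg = c(10, 50, 90, 50), azimuth_deg = c(0, 90, 180, 270),
    thickness_mm = 1))
  nl <- nishii_offset(cup$surface, cup$frame, const)
  sl <- shivanna_offset(cup$surface, cup$frame,
                        shivanna_params(smoothing_iterations = 0),
                        "acetabular")
  expect_lt(max(abs(nl$thickness - sl$thickness)), 1e-9)
  expect_lt(max(abs(nl$contact$vertices - sl$contact$vertices)), 1e-9)
})

test_that("rim-thickened map puts the thickest elements in the rim band", {
  g <- hip_geometry(cup_axis = c(0, 0, 1), coverage = 100, medial_trim = 5,
                    target_element_size = 1.5)
  cup <- generate_acetabulum(g)
  layer <- nishii_offset(cup$surface, cup$frame, default_thickness_map())
  pol <- radial_decomposition(layer$contact$element_centroid, cup$frame)$polar
  expect_gt(pol[which.max(layer$thickness)], 75)
  expect_true(all(layer$thickness > 0))
})

test_that("spherical cup with constant map gives contact radius cup_radius - c", {
  g <- hip_geometry(head_radius = 22, clearance = 3, cup_axis = c(0, 0, 1),
                    coverage = 85, medial_trim = 4, target_element_size = 2)
  cup <- generate_acetabulum(g)
  const <- fit_thickness_map(data.frame(
    polar_deg = c(10, 50, 80, 50), azimuth_deg = c(0, 90, 180, 270),
    thickness_mm = 1.3))
  layer <- nishii_offset(cup$surface, cup$frame, const)
  r <- sqrt(rowSums(layer$contact$vertices^2))
  expect_lt(max(abs(r - (25 - 1.3))), 1e-9)
})

test_that("generated layers satisfy the layer invariants on random draws", {
  set.seed(33)
  for (rep in 1:25) {
    lat <- stats::runif(1, 60, 115)
    ant <- stats::runif(1, 60, 115)
    g <- hip_geometry(head_radius = stats::runif(1, 21, 27),
                      clearance = stats::runif(1, 1, 3),
                      coverage = c(lateral = lat, anterior = ant,
                                   inferior = 95, posterior = 92),
                      target_element_size = 2.5)
    cup <- generate_acetabulum(g)
    which_model <- sample(c("s", "n"), 1L)
    layer <- if (which_model == "s") {
      shivanna_offset(cup$surface, cup$frame,
                      shivanna_params(offset = stats::runif(1, 0.5, 1.5)),
                      "acetabular")
    } else {
      nishii_offset(cup$surface, cup$frame, default_thickness_map())
    }
    expect_true(all(layer$thickness > 0))
    r_sub <- sqrt(rowSums(layer$subchondral$vertices^2))
    r_con <- sqrt(rowSums(layer$contact$vertices^2))
    expect_true(all(r_con < r_sub))  # acetabular contact lies inside subchondral
  }
})

test_that("packaged synthetic thickness map CSV loads and interpolates", {
  path <- system.file("extdata", "thickness_map_synthetic.csv",
                      package = "hipdea")
  samples <- utils::read.csv(path)
  map <- fit_thickness_map(samples)
  expect_lt(max(abs(evaluate_thickness(map, samples$polar_deg,
                                       samples$azimuth_deg) -
                      samples$thickness_mm)), 1e-6)
  # same sites as the packaged default constructor
  expect_equal(map$samples, default_thickness_map()$samples)
})

test_that("offset not smaller than the local radius is rejected", {
  s <- icosphere(0.8, 2)
  fr <- spherical_frame(c(0, 0, 0))
  expect_error(shivanna_offset(s, fr, shivanna_params(offset = 1),
                               "acetabular"), "radius")
})
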