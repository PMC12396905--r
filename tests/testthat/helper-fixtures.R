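# shared fixtures and independent oracles for the test suite

# a stress field with given stresses/areas (bypasses the solver)
mk_field <- function(stress, area = rep(1, length(stress))) {
  structure(list(element_stress = stress, element_area = area,
                 head_translation = c(0, 0, 0), converged = TRUE,
                 residual = 0, iterations = 0L),
            class = "stress_field")
}

mk_sequence <- function(stress_list, area = NULL, dt = 0.1,
                        total_area = NULL) {
  n <- length(stress_list[[1L]])
  if (is.null(area)) area <- rep(1, n)
  if (is.null(total_area)) total_area <- sum(area)
  gait_stress_sequence(lapply(stress_list, mk_field, area = area),
                       dt = dt, total_area = total_area)
}

# random small stress sequence (elements x instances)
random_sequence <- function(n_elem = 20L, n_inst = 7L, dt = NULL) {
  if (is.null(dt)) dt <- stats::runif(1, 0.02, 0.15)
  area <- stats::runif(n_elem, 0.1, 2)
  stress <- lapply(seq_len(n_inst), function(j) {
    p <- stats::runif(n_elem, 0, 12)
    p[stats::runif(n_elem) < 0.3] <- 0  # separated elements
    p
  })
  mk_sequence(stress, area = area, dt = dt,
              total_area = sum(area) * stats::runif(1, 1, 1.5))
}

# independent brute-force implementation of the eight metrics:
# plain double loops straight from the printed definitions
brute_metrics <- function(seq, thr = metric_thresholds()) {
  t_n <- seq$t; dt <- seq$dt; A <- seq$total_area
  n <- length(seq$fields[[1L]]$element_stress)
  p <- function(i, j) seq$fields[[j]]$element_stress[i]
  a <- function(i, j) seq$fields[[j]]$element_area[i]

  abs_peak <- -Inf
  for (j in 1:t_n) for (i in 1:n) abs_peak <- max(abs_peak, p(i, j))

  avg_peak <- 0
  for (j in 1:t_n) {
    mx <- -Inf
    for (i in 1:n) mx <- max(mx, p(i, j))
    avg_peak <- avg_peak + mx / t_n
  }

  dose_max <- -Inf
  for (i in 1:n) {
    d <- 0
    for (j in 1:t_n) d <- d + p(i, j) * dt
    dose_max <- max(dose_max, d)
  }

  ca <- 0
  for (j in 1:t_n) for (i in 1:n) if (p(i, j) > 0) ca <- ca + a(i, j)
  ca <- 100 * ca / (A * t_n)

  avg_st <- 0
  for (j in 1:t_n) {
    num <- 0; den <- 0
    for (i in 1:n) if (p(i, j) > 0) { num <- num + p(i, j) * a(i, j); den <- den + a(i, j) }
    if (den > 0) avg_st <- avg_st + (num / den) / t_n
  }

  sta <- 0
  for (j in 1:t_n) for (i in 1:n)
    if (p(i, j) > thr$suprathreshold_stress) sta <- sta + a(i, j)
  sta <- 100 * sta / (A * t_n)

  maxian <- 0
  for (j in 1:t_n) {
    num <- 0; den <- 0
    for (i in 1:n) if (p(i, j) > thr$maxian_stress) { num <- num + p(i, j) * a(i, j); den <- den + a(i, j) }
    if (den > 0) maxian <- maxian + (num / den) * dt
  }

  num <- 0; den <- 0
  for (i in 1:n) {
    d <- 0; mx <- -Inf
    for (j in 1:t_n) { d <- d + p(i, j) * dt; mx <- max(mx, p(i, j)) }
    if (d > thr$ste_dose) num <- num + a(i, 1L)
    if (mx > thr$ste_stress) den <- den + a(i, 1L)
  }
  ste <- if (den > 0) 100 * num / den else 0

  list(absolute_peak_stress = abs_peak, average_peak_stress = avg_peak,
       peak_stress_time_dose = dose_max, average_contact_area = ca,
       average_stress = avg_st, average_suprathreshold_area = sta,
       maxian_overdose = maxian, ste_contact_area = ste)
}

# congruent sphere-in-hemisphere oracle geometry: acetabular subchondral
# radius `R`, uniform cartilage `h` both sides
oracle_geometry <- function(R = 25, h = 1, element_size = 0.7) {
  hip_geometry(head_radius = R - 2 * h, clearance = 2 * h,
               cup_axis = c(0, 0, 1), coverage = 90, medial_trim = 2,
               target_element_size = element_size)
}

oracle_model <- function(R = 25, h = 1, element_size = 0.7) {
  g <- oracle_geometry(R, h, element_size)
  cup <- generate_acetabulum(g)
  head <- generate_femoral_head(g)
  acet <- shivanna_offset(cup$surface, cup$frame,
                          shivanna_params(offset = h), "acetabular")
  fem <- shivanna_offset(head$surface, head$frame,
                         shivanna_params(offset = h), "femoral")
  dea_model(acet, fem, cup$frame)
}

# small two-pulse profile with analytically known peak times
two_pulse_glp <- function(t1 = 0.2, t2 = 0.8, p1 = 250, p2 = 250,
                          n = 201L) {
  t <- seq(0, 1, length.out = n)
  mag <- 50 + (p1 - 50) * exp(-(t - t1)^2 / (2 * 0.08^2)) +
    (p2 - 50) * exp(-(t - t2)^2 / (2 * 0.08^2))
  jrf <- cbind(0 * t, mag * 0.95, -mag * 0.3)
  angles <- cbind(20 * cos(pi * t), 5 * sin(pi * t), 0 * t)
  gait_profile("two_pulse", t, jrf, angles)
}
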