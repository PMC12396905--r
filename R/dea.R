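#' Cartilage material parameters
#'
#' Isotropic linear elastic cartilage for the bed-of-springs model:
#' Young's modulus 12 MPa, Poisson's ratio 0.43.
#'
#' @param youngs_modulus MPa.
#' @param poisson_ratio dimensionless, in (0, 0.5).
#' @return object of class `material_params`.
#' @export
material_params <- function(youngs_modulus = 12, poisson_ratio = 0.43) {
  stopifnot(youngs_modulus > 0)
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie strictly between 0 and 0.5")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_params")
}

#' Solver settings
#'
#' Convergence and divergence criteria of the quasistatic equilibrium
#' search: equilibrium when the force residual drops below
#' `force_residual_tol`; divergence when the iteration count exceeds
#' `max_iterations` or the displacement step falls below `min_step`.
#'
#' @param force_residual_tol N.
#' @param max_iterations count.
#' @param min_step mm.
#' @return object of class `solver_settings`.
#' @export
solver_settings <- function(force_residual_tol = 1e-6,
                            max_iterations = 400L, min_step = 1e-6) {
  stopifnot(force_residual_tol > 0, max_iterations > 0, min_step > 0)
  structure(list(force_residual_tol = force_residual_tol,
                 max_iterations = as.integer(max_iterations),
                 min_step = min_step),
            class = "solver_settings")
}

#' Per-area spring stiffness of the cartilage bed
#'
#' Confined-compression (aggregate modulus) form of the elastic
#' foundation: k = E (1 - nu) / ((1 + nu)(1 - 2 nu)) / h, with h the
#' combined (series) cartilage thickness along the spring axis. Contact
#' stress is k times the surface interpenetration.
#'
#' @param mat a [material_params()].
#' @param combined_thickness h, mm (> 0); acetabular plus femoral layer
#'   thickness in series.
#' @param law `"confined"` (default aggregate-modulus form) or
#'   `"simple"` (plain E/h).
#' @return stiffness per unit area, MPa/mm.
#' @export
spring_constant <- function(mat, combined_thickness, law = c("confined", "simple")) {
  stopifnot(inherits(mat, "material_params"))
  law <- match.arg(law)
  if (any(combined_thickness <= 0)) stop("combined_thickness must be > 0")
  E <- mat$youngs_modulus; nu <- mat$poisson_ratio
  modulus <- if (law == "confined")
    E * (1 - nu) / ((1 + nu) * (1 - 2 * nu)) else E
  modulus / combined_thickness
}

#' Assemble a DEA contact model
#'
#' Precomputes the spring bed from the two cartilage layers: one spring
#' per acetabular subchondral element, with its axis along the ray from
#' the joint centre through the element centroid (fixed during the
#' solve). Contact stresses and areas are carried on the acetabular
#' subchondral elements. The femoral cartilage outer surface is stored as
#' a radial field about the head centre; when it is spherical with
#' uniform thickness (the default synthetic geometry) a closed-form
#' sphere intersection is used, otherwise the radius along each spring
#' ray is looked up once per instance solve.
#'
#' @param acet_layer acetabular [shivanna_offset()]/[nishii_offset()]
#'   layer.
#' @param femur_layer femoral cartilage layer.
#' @param frame joint [spherical_frame()] (cup centre and axes).
#' @param mat a [material_params()].
#' @param law stiffness law, see [spring_constant()].
#' @return object of class `dea_model`.
#' @export
dea_model <- function(acet_layer, femur_layer, frame,
                      mat = material_params(), law = "confined") {
  stopifnot(inherits(acet_layer, "cartilage_layer"),
            inherits(femur_layer, "cartilage_layer"))
  if (acet_layer$side != "acetabular" || femur_layer$side != "femoral")
    stop("layers must be one acetabular and one femoral")
  ctr <- frame$center
  sub <- acet_layer$subchondral
  a <- sub$element_area
  cen <- sub$element_centroid - matrix(ctr, nrow(sub$faces), 3, byrow = TRUE)
  rad <- sqrt(rowSums(cen^2))
  u <- cen / rad
  # acetabular contact radius along each ray: mean contact-vertex radius
  vc <- acet_layer$contact$vertices -
    matrix(ctr, nrow(acet_layer$contact$vertices), 3, byrow = TRUE)
  rvc <- sqrt(rowSums(vc^2))
  f <- acet_layer$contact$faces
  r_contact <- (rvc[f[, 1L]] + rvc[f[, 2L]] + rvc[f[, 3L]]) / 3

  # femoral contact surface as a radial field about the head centre
  hc <- femur_layer$frame$center
  fv <- femur_layer$contact$vertices -
    matrix(hc, nrow(femur_layer$contact$vertices), 3, byrow = TRUE)
  fr <- sqrt(rowSums(fv^2))
  ff <- femur_layer$contact$faces
  fcen <- femur_layer$contact$element_centroid -
    matrix(hc, nrow(ff), 3, byrow = TRUE)
  fcr <- sqrt(rowSums(fcen^2))
  fdir <- fcen / fcr
  f_elem_r <- (fr[ff[, 1L]] + fr[ff[, 2L]] + fr[ff[, 3L]]) / 3
  spherical <- (max(f_elem_r) - min(f_elem_r) < 1e-9) &&
    (max(femur_layer$thickness) - min(femur_layer$thickness) < 1e-9)

  structure(list(
    frame = frame, mat = mat, law = law,
    area = a, u = u, r_acet = r_contact,
    h_acet = acet_layer$thickness,
    head_center = hc,
    femur_dir = fdir, femur_r = f_elem_r,
    femur_h = femur_layer$thickness,
    spherical_femur = spherical,
    femur_r0 = stats::median(f_elem_r),
    femur_h0 = stats::median(femur_layer$thickness),
    acet_layer = acet_layer, femur_layer = femur_layer
  ), class = "dea_model")
}

#' @export
print.dea_model <- function(x, ...) {
  cat(sprintf(
    "dea_model: %d springs, acetabular area %.0f mm^2, femur %s\n",
    length(x$area), sum(x$area),
    if (x$spherical_femur) "spherical (fast path)" else "radial lookup"
  ))
  invisible(x)
}

#' Pose the femoral surface
#'
#' Rotation about the head centre by flexion (about +Z), then abduction
#' (about +X), then internal rotation (about +Y), followed by a
#' translation.
#'
#' @param surface a [tri_surface()] (femoral).
#' @param frame head [spherical_frame()] (rotation centre).
#' @param angles degrees, c(flexion, abduction, internal rotation).
#' @param translation mm 3-vector.
#' @return The posed `tri_surface`.
#' @export
pose_femur <- function(surface, frame, angles = c(0, 0, 0),
                       translation = c(0, 0, 0)) {
  stopifnot(inherits(surface, "tri_surface"))
  R <- .pose_rotation(angles)
  ctr <- matrix(frame$center, nrow(surface$vertices), 3, byrow = TRUE)
  surface$vertices <- (surface$vertices - ctr) %*% t(R) + ctr +
    matrix(as.numeric(translation), nrow(surface$vertices), 3, byrow = TRUE)
  .refresh_elements(surface)
}

.pose_rotation <- function(angles) {
  .rot_y(angles[3L]) %*% .rot_x(angles[2L]) %*% .rot_z(angles[1L])
}

# femoral outer radius along each spring ray, for a given pose.
# Constant on the fast path; otherwise nearest-direction lookup of the
# radial field in the femur body frame (done once per instance solve).
.femur_ray_radius <- function(model, angles, translation = c(0, 0, 0)) {
  if (model$spherical_femur)
    return(list(r = rep(model$femur_r0, length(model$area)),
                h = rep(model$femur_h0, length(model$area))))
  R <- .pose_rotation(angles)
  hc <- model$head_center + as.numeric(translation)
  # approximate contact direction: from head centre toward the
  # acetabular contact point
  pts <- model$u * model$r_acet +
    matrix(model$frame$center - hc, length(model$area), 3, byrow = TRUE)
  w <- pts / sqrt(rowSums(pts^2))
  w_body <- w %*% R  # R^T applied to rows
  sim <- w_body %*% t(model$femur_dir)
  nearest <- max.col(sim)
  list(r = model$femur_r[nearest], h = model$femur_h[nearest])
}

#' Surface interpenetrations along the spring axes
#'
#' For each acetabular element, the overlap (mm) between the posed
#' femoral cartilage outer surface and the acetabular cartilage contact
#' surface along the spring ray; separations are reported as 0 (no
#' tension).
#'
#' @param model a [dea_model()].
#' @param translation head translation, mm 3-vector.
#' @param angles GLP angles (degrees), pose of the femur.
#' @return numeric vector of penetrations (mm, >= 0).
#' @export
penetrations <- function(model, translation = c(0, 0, 0),
                         angles = c(0, 0, 0)) {
  stopifnot(inherits(model, "dea_model"))
  fr <- .femur_ray_radius(model, angles)
  .penetrations_fast(model, as.numeric(translation), fr$r)
}

# core penetration kernel: ray-sphere along each spring axis with
# per-ray femoral radius
.penetrations_fast <- function(model, translation, femur_r) {
  h <- model$head_center + translation - model$frame$center
  b <- as.numeric(model$u %*% h)
  perp2 <- sum(h^2) - b^2
  disc <- femur_r^2 - perp2
  hit <- disc > 0
  s_far <- rep(-Inf, length(b))
  s_far[hit] <- b[hit] + sqrt(disc[hit])
  delta <- pmax(0, s_far - model$r_acet)
  # overlaps below coordinate roundoff are genuine separations
  delta[delta < 1e-12] <- 0
  delta
}

#' Residual force of the spring bed
#'
#' R = F_applied - sum_i p_i a_i u_i, with p_i = k_i delta_i the
#' compressive spring stress, a_i the element area and u_i the spring
#' axis unit vector (joint centre toward element); at equilibrium the
#' summed spring reactions balance the applied joint load.
#'
#' @param model a [dea_model()].
#' @param translation head translation, mm.
#' @param force applied JRF, N 3-vector.
#' @param angles GLP angles, degrees.
#' @return residual 3-vector, N.
#' @export
residual_force <- function(model, translation, force, angles = c(0, 0, 0)) {
  stopifnot(inherits(model, "dea_model"))
  fr <- .femur_ray_radius(model, angles)
  k <- spring_constant(model$mat, model$h_acet + fr$h, model$law)
  delta <- .penetrations_fast(model, as.numeric(translation), fr$r)
  p <- k * delta
  as.numeric(force) - as.numeric(crossprod(model$u, p * model$area))
}

#' Solve one quasistatic load instance
#'
#' Levenberg-Marquardt search for the head translation that balances the
#' applied joint reaction force against the spring bed. Convergence:
#' residual norm below the force tolerance. Divergence: iteration budget
#' exhausted, or the displacement step shrinking below the minimum step
#' (the subluxation signature when coverage is insufficient for the
#' applied force).
#'
#' @param model a [dea_model()].
#' @param force applied JRF, N 3-vector (one instance).
#' @param angles GLP angles, degrees.
#' @param settings a [solver_settings()].
#' @param init initial head translation, mm.
#' @return A `stress_field` on convergence (fields: `element_stress` MPa,
#'   `element_area` mm^2, `head_translation`, `converged`, `residual`,
#'   `iterations`) or a `dea_divergence` (fields: `reason`, `residual`,
#'   `iterations`).
#' @export
solve_instance <- function(model, force, angles = c(0, 0, 0),
                           settings = solver_settings(),
                           init = c(0, 0, 0)) {
  stopifnot(inherits(model, "dea_model"), inherits(settings, "solver_settings"))
  force <- as.numeric(force)
  if (any(!is.finite(force))) stop("non-finite applied force")
  fr <- .femur_ray_radius(model, angles)
  k <- spring_constant(model$mat, model$h_acet + fr$h, model$law)
  ka <- k * model$area
  c0 <- model$frame$center
  hc0 <- model$head_center
  res_fun <- function(t) {
    delta <- .penetrations_fast(model, t, fr$r)
    force - as.numeric(crossprod(model$u, ka * delta))
  }
  # central-difference Jacobian; the step straddles the contact-set kink
  # so marginal elements do not destabilize the Newton direction
  jac_fun <- function(t) {
    J <- matrix(0, 3L, 3L)
    hstep <- 1e-6
    for (j in 1:3) {
      tp <- t; tm <- t
      tp[j] <- tp[j] + hstep; tm[j] <- tm[j] - hstep
      J[, j] <- (res_fun(tp) - res_fun(tm)) / (2 * hstep)
    }
    J
  }

  t_cur <- as.numeric(init)
  r_cur <- res_fun(t_cur)
  if (any(!is.finite(r_cur))) stop("non-finite residual force")
  lambda <- 1e-4
  iters <- 0L
  reason <- NULL
  while (TRUE) {
    if (sqrt(sum(r_cur^2)) < settings$force_residual_tol) break
    if (iters >= settings$max_iterations) { reason <- "max_iterations"; break }
    J <- jac_fun(t_cur)
    if (all(abs(J) < 1e-12)) {
      # no contact anywhere: pull the head along the load to seat it
      step <- force / max(1e-9, sqrt(sum(force^2))) * 0.1
    } else {
      g <- crossprod(J, r_cur)
      A <- crossprod(J)
      step <- tryCatch(
        -solve(A + lambda * diag(pmax(diag(A), 1e-12)), g)[, 1L],
        error = function(e) -g[, 1L] / max(1e-9, sqrt(sum(g^2))) * 1e-3
      )
    }
    t_new <- t_cur + step
    r_new <- res_fun(t_new)
    iters <- iters + 1L
    accepted <- sum(r_new^2) < sum(r_cur^2)
    if (accepted) {
      t_cur <- t_new; r_cur <- r_new
      lambda <- max(1e-12, lambda / 3)
    } else {
      lambda <- lambda * 4
    }
    if (sqrt(sum(r_cur^2)) < settings$force_residual_tol) break
    if (sqrt(sum(step^2)) < settings$min_step) { reason <- "min_step"; break }
  }
  resid <- sqrt(sum(r_cur^2))
  if (!is.null(reason)) {
    return(structure(list(reason = reason, residual = resid,
                          iterations = iters),
                     class = "dea_divergence"))
  }
  delta <- .penetrations_fast(model, t_cur, fr$r)
  structure(list(
    element_stress = k * delta,
    element_area = model$area,
    head_translation = t_cur,
    converged = TRUE,
    residual = resid,
    iterations = iters
  ), class = "stress_field")
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf(
    "stress_field: peak %.3f MPa, contact %.0f/%d elements, residual %.2e N (%d iters)\n",
    max(x$element_stress), sum(x$element_stress > 0),
    length(x$element_stress), x$residual, x$iterations
  ))
  invisible(x)
}

#' @export
print.dea_divergence <- function(x, ...) {
  cat(sprintf("dea_divergence: %s (residual %.3g N after %d iterations)\n",
              x$reason, x$residual, x$iterations))
  invisible(x)
}

#' Solve a seven-instance gait sequence
#'
#' Solves the load instances in order with warm starts (each instance
#' initialized at the previous equilibrium translation). The sequence is
#' all-or-nothing: if any instance diverges, the whole sequence is
#' reported as a `sequence_divergence` listing the failing instance
#' indices, and no stress results are returned.
#'
#' @param model a [dea_model()].
#' @param instances a [discretize_gait()] result.
#' @param settings a [solver_settings()].
#' @return A `gait_stress_sequence` (fields: `fields` list of
#'   `stress_field`, `t`, `dt`, `total_area`) or a
#'   `sequence_divergence` (field `failed`: instance indices).
#' @export
solve_sequence <- function(model, instances, settings = solver_settings()) {
  stopifnot(inherits(model, "dea_model"), inherits(instances, "load_instances"))
  n <- length(instances$time)
  fields <- vector("list", n)
  failed <- integer(0)
  t_init <- c(0, 0, 0)
  for (j in seq_len(n)) {
    out <- solve_instance(model, instances$force[j, ], instances$angles[j, ],
                          settings, init = t_init)
    if (inherits(out, "dea_divergence")) {
      failed <- c(failed, j)
    } else {
      fields[[j]] <- out
      t_init <- out$head_translation
    }
  }
  if (length(failed) > 0L) {
    return(structure(list(failed = failed, n = n),
                     class = "sequence_divergence"))
  }
  gait_stress_sequence(fields, instances$dt, sum(model$area))
}

#' Gait stress sequence container
#'
#' @param fields list of `stress_field` objects (one per instance).
#' @param dt inter-instance time increment, s.
#' @param total_area total acetabular area A, mm^2.
#' @return object of class `gait_stress_sequence`.
#' @export
gait_stress_sequence <- function(fields, dt, total_area) {
  stopifnot(length(fields) >= 1L, dt > 0, total_area > 0)
  structure(list(fields = fields, t = length(fields), dt = dt,
                 total_area = total_area),
            class = "gait_stress_sequence")
}

#' @export
print.gait_stress_sequence <- function(x, ...) {
  pk <- max(vapply(x$fields, function(f) max(f$element_stress), 0))
  cat(sprintf(
    "gait_stress_sequence: %d instances, dt %.4f s, A %.0f mm^2, peak %.3f MPa\n",
    x$t, x$dt, x$total_area, pk
  ))
  invisible(x)
}

#' @export
print.sequence_divergence <- function(x, ...) {
  cat(sprintf("sequence_divergence: instances %s diverged (sequence excluded)\n",
              paste(x$failed, collapse = ", ")))
  invisible(x)
}
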