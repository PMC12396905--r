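#' Rim coverage profile
#'
#' The acetabular cup is modelled as a spherical cap about the cup's deep
#' axis, trimmed at a rim polar angle that may vary with azimuth. Azimuth
#' 0 deg points toward the superolateral roof, +90 deg anterior, 180 deg
#' inferior, 270 deg posterior (around the deep axis). Coverage is the rim
#' polar angle measured from the deep axis: 90 deg is a hemisphere, larger
#' values wrap toward the joint opening, smaller values are shallow
#' (dysplastic) cups.
#'
#' @param x a single polar angle (uniform coverage), a named numeric
#'   vector with any of `lateral`, `anterior`, `inferior`, `posterior`
#'   anchors (degrees, piecewise-linear periodic interpolation), a
#'   two-column table (`azimuth`, `polar`), or a function
#'   `f(azimuth_deg) -> polar_deg`.
#' @return A vectorized function of azimuth (degrees) returning the rim
#'   polar angle (degrees).
#' @export
rim_coverage <- function(x) {
  if (is.function(x)) {
    f <- x
  } else if (is.numeric(x) && length(x) == 1L && is.null(names(x))) {
    val <- as.numeric(x)
    f <- function(azimuth) rep(val, length(azimuth))
  } else if (is.numeric(x) && !is.null(names(x))) {
    anchor_az <- c(lateral = 0, anterior = 90, inferior = 180, posterior = 270)
    known <- intersect(names(x), names(anchor_az))
    if (length(known) == 0L) stop("unrecognized rim coverage anchor names")
    f <- .periodic_linear(anchor_az[known], as.numeric(x[known]))
  } else if (is.data.frame(x) || (is.matrix(x) && ncol(x) == 2L)) {
    x <- as.data.frame(x)
    f <- .periodic_linear(x[[1L]], x[[2L]])
  } else {
    stop("cannot interpret rim coverage specification")
  }
  probe <- f(seq(0, 359, by = 1))
  if (any(!is.finite(probe)) || any(probe <= 0) || any(probe >= 120))
    stop("rim coverage must lie within (0, 120) degrees for all azimuths")
  f
}

# piecewise-linear periodic interpolation on [0, 360)
.periodic_linear <- function(az, val) {
  az <- az %% 360
  o <- order(az)
  az <- az[o]; val <- val[o]
  if (anyDuplicated(az)) stop("duplicate rim coverage anchor azimuths")
  az_ext <- c(az, az[1L] + 360)
  val_ext <- c(val, val[1L])
  function(azimuth) {
    a <- azimuth %% 360
    a[a < az_ext[1L]] <- a[a < az_ext[1L]] + 360
    stats::approx(az_ext, val_ext, xout = a, rule = 2)$y
  }
}

#' Parametric hip geometry
#'
#' Parameters of a single hip in the pelvis-fixed frame (+X anterior,
#' +Y superior, +Z lateral toward the studied hip; left hips are mirrored
#' to this right-hip convention before processing). The femoral head
#' centre is at `center`; the acetabular cup is concentric with radius
#' `head_radius + clearance`.
#'
#' @param head_radius femoral head subchondral radius, mm.
#' @param clearance nominal joint space, mm; default 2 so that two 1 mm
#'   cartilage layers exactly fill the joint when congruent.
#' @param inclination,anteversion cup opening direction, degrees: the
#'   opening axis starts lateral (+Z), is tilted inferiorly by
#'   `inclination` and anteriorly by `anteversion`. Ignored when
#'   `cup_axis` is given.
#' @param cup_axis optional explicit opening direction (unit 3-vector).
#' @param coverage rim coverage specification, see [rim_coverage()].
#' @param medial_trim polar angle (degrees from the deep axis) at which
#'   the cup is trimmed medially; its superior edge is the medial sourcil
#'   proxy used for the acetabular index.
#' @param target_element_size mesh target edge length, mm.
#' @param head_noise amplitude (mm) of radial perturbation applied to
#'   femoral head vertices (0 = perfect sphere).
#' @param center head centre, mm.
#' @return An object of class `hip_geometry`.
#' @export
hip_geometry <- function(head_radius = 25, clearance = 2,
                         inclination = 45, anteversion = 20,
                         cup_axis = NULL,
                         coverage = c(lateral = 100, anterior = 100,
                                      inferior = 95, posterior = 92),
                         medial_trim = 10,
                         target_element_size = 1.5,
                         head_noise = 0,
                         center = c(0, 0, 0)) {
  stopifnot(head_radius > 0, clearance >= 0, target_element_size > 0,
            medial_trim > 0, medial_trim < 60, head_noise >= 0)
  if (is.null(cup_axis)) {
    ia <- inclination * pi / 180
    av <- anteversion * pi / 180
    cup_axis <- c(cos(ia) * sin(av), -sin(ia), cos(ia) * cos(av))
  }
  cup_axis <- .normalize(as.numeric(cup_axis))
  deep <- -cup_axis
  # roof azimuth reference: superior direction projected off the deep axis
  e1 <- .normalize(c(0, 1, 0) - sum(c(0, 1, 0) * deep) * deep)
  frame <- spherical_frame(center, .complete_from(e1, deep))
  structure(list(
    head_radius = head_radius,
    cup_radius = head_radius + clearance,
    clearance = clearance,
    cup_frame = frame,
    coverage = rim_coverage(coverage),
    medial_trim = medial_trim,
    target_element_size = target_element_size,
    head_noise = head_noise,
    center = as.numeric(center)
  ), class = "hip_geometry")
}

# right-handed triad with given first and third axes
.complete_from <- function(e1, e3) {
  e2 <- c(
    e3[2L] * e1[3L] - e3[3L] * e1[2L],
    e3[3L] * e1[1L] - e3[1L] * e1[3L],
    e3[1L] * e1[2L] - e3[2L] * e1[1L]
  )
  cbind(e1, .normalize(e2), e3)
}

#' @export
print.hip_geometry <- function(x, ...) {
  m <- radiographic_measures_params(x)
  cat(sprintf(
    "hip_geometry: head R %.1f mm, cup R %.1f mm | LCEA %.1f, AI %.1f, ACEA %.1f, AAA %.1f, FHEI %.1f\n",
    x$head_radius, x$cup_radius, m$LCEA, m$AI, m$ACEA, m$AAA, m$FHEI
  ))
  invisible(x)
}

#' Generate the acetabular subchondral surface
#'
#' Structured spherical-coordinate mesh of the lunate cup: polar rings
#' from the medial trim to the (azimuth-dependent) rim, so the mesh rim
#' lies exactly on the parametric rim curve. Normals are oriented toward
#' the head centre (into the joint space).
#'
#' @param geom a [hip_geometry()].
#' @param seed integer seed (the cup itself is deterministic; kept for
#'   interface symmetry with [generate_femoral_head()]).
#' @return list with `surface` (a [tri_surface()]), `frame` (the cup
#'   [spherical_frame()]), `rim_index` (vertex indices of the rim ring)
#'   and `medial_index` (vertex indices of the medial trim ring).
#' @export
generate_acetabulum <- function(geom, seed = 1L) {
  stopifnot(inherits(geom, "hip_geometry"))
  R <- geom$cup_radius
  es <- geom$target_element_size
  cov <- geom$coverage
  az_probe <- seq(0, 359, by = 1)
  th_rim <- cov(az_probe)
  if (any(th_rim <= geom$medial_trim))
    stop("rim coverage does not clear the medial trim for all azimuths")
  th_mid <- (mean(th_rim) + geom$medial_trim) / 2
  n_az <- max(16L, ceiling(2 * pi * R * sin(th_mid * pi / 180) / es))
  n_s <- max(3L, ceiling(R * (mean(th_rim) - geom$medial_trim) * pi / 180 / es))
  phi <- seq(0, 360, length.out = n_az + 1L)[-(n_az + 1L)]
  th_rim_g <- cov(phi)
  s <- seq(0, 1, length.out = n_s + 1L)
  # vertices: ring-major, azimuth within ring
  th <- outer(s, th_rim_g - geom$medial_trim) + geom$medial_trim  # (n_s+1) x n_az
  thr <- th * pi / 180
  phr <- matrix(phi * pi / 180, n_s + 1L, n_az, byrow = TRUE)
  local <- cbind(
    R * as.vector(t(sin(thr) * cos(phr))),
    R * as.vector(t(sin(thr) * sin(phr))),
    R * as.vector(t(cos(thr)))
  )
  verts <- local %*% t(geom$cup_frame$axes) +
    matrix(geom$center, nrow(local), 3, byrow = TRUE)
  idx <- function(i, j) (i - 1L) * n_az + ((j - 1L) %% n_az) + 1L
  i <- rep(seq_len(n_s), each = n_az)
  j <- rep(seq_len(n_az), times = n_s)
  f1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  f2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  surf <- tri_surface(verts, rbind(f1, f2))
  surf <- orient_surface(surf, geom$center, "toward")
  list(
    surface = surf,
    frame = geom$cup_frame,
    rim_index = idx(rep(n_s + 1L, n_az), seq_len(n_az)),
    medial_index = idx(rep(1L, n_az), seq_len(n_az))
  )
}

#' Generate the femoral head subchondral surface
#'
#' Near-spherical patch about the cup's deep axis covering the cup's
#' angular extent plus margin, meshed with ring-adaptive azimuth counts so
#' the mean edge length tracks `target_element_size`. Optional seeded
#' radial noise produces controlled asphericity. Normals point away from
#' the head centre (into the joint space).
#'
#' @param geom a [hip_geometry()].
#' @param seed integer seed for the radial noise.
#' @param margin extra polar extent beyond the rim, degrees.
#' @return list with `surface` and `frame` (head frame, same axes as the
#'   cup frame, centred on the head centre).
#' @export
generate_femoral_head <- function(geom, seed = 1L, margin = 20) {
  stopifnot(inherits(geom, "hip_geometry"))
  R <- geom$head_radius
  es <- geom$target_element_size
  th_max <- min(160, max(geom$coverage(seq(0, 359, by = 1))) + margin)
  d_th <- es / R  # radians
  n_rings <- max(3L, round(th_max * pi / 180 / d_th))
  thetas <- seq(0, th_max * pi / 180, length.out = n_rings + 1L)
  rings <- list(matrix(c(0, 0, 1), 1L, 3L))  # pole (local coords, unit)
  for (k in 2:(n_rings + 1L)) {
    th <- thetas[k]
    n_k <- max(6L, round(2 * pi * sin(th) / d_th))
    ph <- seq(0, 2 * pi, length.out = n_k + 1L)[-(n_k + 1L)]
    rings[[k]] <- cbind(sin(th) * cos(ph), sin(th) * sin(ph),
                        rep(cos(th), n_k))
  }
  counts <- vapply(rings, nrow, 0L)
  offsets <- cumsum(c(0L, counts[-length(counts)]))
  verts_u <- do.call(rbind, rings)
  faces <- vector("list", n_rings)
  for (k in seq_len(n_rings)) {
    faces[[k]] <- .stitch_rings(rings[[k]], rings[[k + 1L]],
                                offsets[k], offsets[k + 1L])
  }
  faces <- do.call(rbind, faces)
  radii <- rep(R, nrow(verts_u))
  if (geom$head_noise > 0) {
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    radii <- radii + geom$head_noise * (2 * stats::runif(nrow(verts_u)) - 1)
  }
  verts <- (verts_u * radii) %*% t(geom$cup_frame$axes) +
    matrix(geom$center, nrow(verts_u), 3, byrow = TRUE)
  surf <- tri_surface(verts, faces)
  surf <- orient_surface(surf, geom$center, "away")
  list(surface = surf,
       frame = spherical_frame(geom$center, geom$cup_frame$axes))
}

# triangulate between two closed rings of unit points (greedy shortest-edge walk)
.stitch_rings <- function(a, b, off_a, off_b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 1L) {
    # pole fan
    j <- seq_len(nb)
    return(cbind(off_a + 1L, off_b + j, off_b + (j %% nb) + 1L))
  }
  faces <- matrix(0L, na + nb, 3L)
  ia <- 0L; ib <- 0L; nf <- 0L
  d2 <- function(p, q) sum((p - q)^2)
  while (ia < na || ib < nb) {
    a_cur <- a[(ia %% na) + 1L, ]; b_cur <- b[(ib %% nb) + 1L, ]
    a_nxt <- a[((ia + 1L) %% na) + 1L, ]; b_nxt <- b[((ib + 1L) %% nb) + 1L, ]
    adv_a <- ia < na && (ib >= nb || d2(a_nxt, b_cur) <= d2(b_nxt, a_cur))
    nf <- nf + 1L
    if (adv_a) {
      faces[nf, ] <- c(off_a + (ia %% na) + 1L,
                       off_a + ((ia + 1L) %% na) + 1L,
                       off_b + (ib %% nb) + 1L)
      ia <- ia + 1L
    } else {
      faces[nf, ] <- c(off_b + (ib %% nb) + 1L,
                       off_a + (ia %% na) + 1L,
                       off_b + ((ib + 1L) %% nb) + 1L)
      ib <- ib + 1L
    }
  }
  faces[seq_len(nf), , drop = FALSE]
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate periacetabular osteotomy (PAO)
#'
#' Rigid reorientation of the acetabular cup about the femoral head
#' centre: the cup frame (opening axis and azimuth reference) is rotated,
#' the cup radius and coverage profile (expressed in the cup frame) are
#' unchanged.
#'
#' @param geom a [hip_geometry()].
#' @param rotation either three angles (degrees, each within +/-45)
#'   applied as Rz(rz) Ry(ry) Rx(rx) about the pelvis axes, or a 3 x 3
#'   rotation matrix.
#' @return The reoriented `hip_geometry`.
#' @export
simulate_pao <- function(geom, rotation) {
  stopifnot(inherits(geom, "hip_geometry"))
  if (is.matrix(rotation)) {
    R <- rotation
    if (max(abs(crossprod(R) - diag(3))) > 1e-9 || det(R) < 0)
      stop("rotation must be a proper rotation matrix")
  } else {
    rotation <- as.numeric(rotation)
    stopifnot(length(rotation) == 3L)
    if (any(abs(rotation) > 45))
      stop("PAO reorientation angles must be within +/-45 degrees")
    R <- .rot_z(rotation[3L]) %*% .rot_y(rotation[2L]) %*% .rot_x(rotation[1L])
  }
  geom$cup_frame <- spherical_frame(geom$cup_frame$center,
                                    R %*% geom$cup_frame$axes)
  geom
}

#' Radiographic coverage measures from a rim curve
#'
#' Computes LCEA, AI, ACEA, AAA and FHEI from a 3D acetabular rim curve
#' by orthographic projection about the head centre (neutral pelvic
#' alignment, no magnification). Conventions: LCEA is the frontal-plane
#' angle between +Y (superior) and the ray to the superior rim crossing of
#' the frontal plane, positive toward lateral; ACEA the sagittal-plane
#' analogue toward anterior; AI the frontal inclination of the line from
#' the medial sourcil point to the LCEA rim point, positive when the roof
#' slopes up laterally; AAA the axial-plane angle of the anterior -
#' posterior rim chord relative to the sagittal axis, positive for
#' anteversion; FHEI the percentage of frontal head width lateral to the
#' LCEA rim point.
#'
#' @param cup a [tri_surface()] of the cup (rim extracted as the longest
#'   boundary loop) or an ordered matrix of rim points (closed polyline).
#' @param head_center head centre (mm).
#' @param head_radius head radius (mm), used for FHEI.
#' @param medial_point optional 3-vector: the medial sourcil point for
#'   AI. When `cup` is a mesh with an inner (medial trim) boundary loop,
#'   its superior-most vertex is used; otherwise AI is `NA`.
#' @return list with elements `LCEA`, `AI`, `ACEA`, `AAA`, `FHEI`
#'   (degrees; FHEI in percent).
#' @export
radiographic_measures <- function(cup, head_center, head_radius,
                                  medial_point = NULL) {
  head_center <- as.numeric(head_center)
  if (inherits(cup, "tri_surface")) {
    loops <- boundary_loops(cup)
    if (length(loops) == 0L) stop("rim curve degenerate: no boundary loop")
    len <- vapply(loops, function(ix) {
      p <- cup$vertices[ix, , drop = FALSE]
      sum(sqrt(rowSums((p - p[c(2:nrow(p), 1L), , drop = FALSE])^2)))
    }, 0)
    rim <- cup$vertices[loops[[which.max(len)]], , drop = FALSE]
    if (is.null(medial_point) && length(loops) > 1L) {
      inner <- cup$vertices[loops[[which.min(len)]], , drop = FALSE]
      medial_point <- inner[which.max(inner[, 2L]), ]
    }
  } else {
    rim <- as.matrix(cup)
  }
  if (nrow(rim) < 3L) stop("rim curve degenerate: fewer than 3 points")
  p <- rim - matrix(head_center, nrow(rim), 3, byrow = TRUE)

  # superior crossing of the frontal plane (x = 0)
  lat <- .plane_crossing(p, 1L)
  L <- if (nrow(lat) > 0L) lat[which.max(lat[, 2L]), ] else p[which.max(p[, 2L]), ]
  lcea <- atan2(L[3L], L[2L]) * 180 / pi
  # anterior crossing of the sagittal plane (z = 0)
  ant <- .plane_crossing(p, 3L)
  A <- if (nrow(ant) > 0L) ant[which.max(ant[, 1L]), ] else p[which.max(p[, 1L]), ]
  acea <- atan2(A[1L], A[2L]) * 180 / pi
  # axial anterior-posterior rim chord
  pa <- p[which.max(p[, 1L]), ]
  pp <- p[which.min(p[, 1L]), ]
  aaa <- atan2(-(pa[3L] - pp[3L]), pa[1L] - pp[1L]) * 180 / pi
  fhei <- 100 * min(1, max(0, (head_radius - L[3L]) / (2 * head_radius)))
  ai <- NA_real_
  if (!is.null(medial_point)) {
    M <- as.numeric(medial_point) - head_center
    ai <- atan2(L[2L] - M[2L], L[3L] - M[3L]) * 180 / pi
  }
  list(LCEA = lcea, AI = ai, ACEA = acea, AAA = aaa, FHEI = fhei)
}

# crossings of a closed polyline with the plane {coordinate k == 0}
.plane_crossing <- function(p, k) {
  q <- p[c(2:nrow(p), 1L), , drop = FALSE]
  s <- p[, k] * q[, k]
  hit <- which(s < 0)
  out <- matrix(0, length(hit), 3L)
  for (m in seq_along(hit)) {
    i <- hit[m]
    w <- p[i, k] / (p[i, k] - q[i, k])
    out[m, ] <- p[i, ] + w * (q[i, ] - p[i, ])
  }
  on_plane <- which(p[, k] == 0)
  if (length(on_plane) > 0L) out <- rbind(out, p[on_plane, , drop = FALSE])
  out
}

#' Boundary loops of an open surface
#'
#' @param surface a [tri_surface()].
#' @return list of integer vectors: ordered vertex indices of each closed
#'   boundary loop.
#' @export
boundary_loops <- function(surface) {
  f <- surface$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "_")
  tab <- table(key)
  bkey <- names(tab)[tab == 1L]
  be <- e[match(bkey, key), , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  nxt <- be[, 2L]; names(nxt) <- be[, 1L]
  loops <- list()
  used <- rep(FALSE, nrow(be))
  starts <- be[, 1L]
  for (i in seq_along(starts)) {
    if (used[i]) next
    loop <- integer(0)
    v <- starts[i]
    repeat {
      loop <- c(loop, v)
      j <- which(be[, 1L] == v & !used)
      if (length(j) == 0L) break
      used[j[1L]] <- TRUE
      v <- be[j[1L], 2L]
      if (v == starts[i]) break
    }
    if (length(loop) >= 3L) loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Radiographic measures from the parametric rim
#'
#' Evaluates [radiographic_measures()] on a densely sampled parametric
#' rim curve of a [hip_geometry()] (no meshing involved).
#'
#' @param geom a [hip_geometry()].
#' @param n_samples number of azimuth samples along the rim.
#' @return As [radiographic_measures()].
#' @export
radiographic_measures_params <- function(geom, n_samples = 720L) {
  stopifnot(inherits(geom, "hip_geometry"))
  phi <- seq(0, 360, length.out = n_samples + 1L)[-(n_samples + 1L)]
  th <- geom$coverage(phi)
  rim <- spherical_to_cartesian(rep(geom$cup_radius, n_samples), th, phi,
                                geom$cup_frame)
  M <- spherical_to_cartesian(geom$cup_radius, geom$medial_trim, 0,
                              geom$cup_frame)
  radiographic_measures(rim, geom$center, geom$head_radius,
                        medial_point = as.numeric(M))
}

#' Calibrate rim coverage anchors to target LCEA / ACEA
#'
#' Solves (by 1D root finding on the parametric measures, iterated twice
#' for the weak cross-coupling) for the lateral and anterior coverage
#' anchors that reproduce target LCEA and ACEA values, keeping the
#' inferior and posterior anchors fixed.
#'
#' @param geom a [hip_geometry()] providing axis/radii defaults.
#' @param target_lcea,target_acea target angles, degrees.
#' @param inferior,posterior fixed anchors, degrees.
#' @return A `hip_geometry` whose parametric LCEA/ACEA match the targets.
#' @export
calibrate_coverage <- function(geom, target_lcea, target_acea,
                               inferior = 95, posterior = 92) {
  lat <- 100; ant <- 100
  mk <- function(lat, ant) {
    g <- geom
    g$coverage <- rim_coverage(c(lateral = lat, anterior = ant,
                                 inferior = inferior, posterior = posterior))
    g
  }
  lo <- geom$medial_trim + 25
  hi <- 119.5
  solve1 <- function(f, fallback) {
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi < 0)
      return(stats::uniroot(f, c(lo, hi), tol = 1e-3)$root)
    # target outside the achievable range for this axis: take the
    # closest achievable endpoint
    if (abs(flo) < abs(fhi)) lo else hi
  }
  for (pass in 1:3) {
    lat <- solve1(function(v)
      radiographic_measures_params(mk(v, ant))$LCEA - target_lcea, lat)
    ant <- solve1(function(v)
      radiographic_measures_params(mk(lat, v))$ACEA - target_acea, ant)
  }
  mk(lat, ant)
}

#' Default cohort configuration
#'
#' Sampling distributions for the synthetic dysplastic cohort: covariates
#' match the study population (age 34.6 +/- 6.4 yr, weight 72.5 +/- 14.2
#' kg, height 1.69 +/- 0.08 m, 16/22 female), pre-operative LCEA/ACEA
#' span dysplastic ranges and post-operative targets sit in healthy
#' ranges, reached through a simulated PAO reorientation with
#' under/over-correction noise.
#'
#' @param ... overrides of individual entries.
#' @return named list of configuration values.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    age_mean = 34.6, age_sd = 6.4, age_range = c(18, 60),
    weight_mean = 72.5, weight_sd = 14.2, weight_range = c(42, 120),
    height_mean = 1.69, height_sd = 0.08, height_range = c(1.45, 1.95),
    female_prob = 16 / 22,
    head_radius_mean = 24, head_radius_sd = 1.2, head_radius_range = c(20, 28),
    clearance = 2,
    inclination_mean = 45, inclination_sd = 4,
    anteversion_mean = 20, anteversion_sd = 5,
    pre_lcea_mean = 17, pre_lcea_sd = 7.4, pre_lcea_range = c(0, 28),
    pre_acea_mean = 21.4, pre_acea_sd = 12, pre_acea_range = c(2, 38),
    post_lcea_mean = 28.6, post_lcea_sd = 5.2, post_lcea_range = c(22, 40),
    post_acea_mean = 31.8, post_acea_sd = 9.5, post_acea_range = c(24, 44),
    correction_noise_sd = 2,
    inferior_anchor = 95, posterior_anchor = 92,
    target_element_size = 1.5,
    bilateral = TRUE
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

.rtruncnorm <- function(n, mean, sd, range) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1L, mean, sd)
      if (v >= range[1L] && v <= range[2L]) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic dysplastic cohort with simulated PAO
#'
#' Draws `n` subjects (plus one extra hip for the first subject when
#' `config$bilateral` is `TRUE`, emulating a bilateral case) with
#' covariates and pre-operative coverage from the configured
#' distributions; the post-operative geometry is obtained from the
#' pre-operative one by [simulate_pao()] with rotations solved to reach
#' the drawn post-operative LCEA/ACEA targets, plus correction noise.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param config see [cohort_config()].
#' @return list of hip records, each with `hip_id`, `subject_id`, `side`,
#'   covariates, `pre_geometry`/`post_geometry` ([hip_geometry()]) and
#'   `pre_measures`/`post_measures`.
#' @export
generate_cohort <- function(n = 22L, seed = 1L, config = cohort_config()) {
  stopifnot(n >= 1L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  cfg <- config
  hips <- list()
  n_hips <- n + as.integer(isTRUE(cfg$bilateral))
  subject_of <- c(seq_len(n), if (isTRUE(cfg$bilateral)) 1L)
  # subject covariates
  sex <- ifelse(stats::runif(n) < cfg$female_prob, "F", "M")
  age <- .rtruncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range)
  weight <- .rtruncnorm(n, cfg$weight_mean, cfg$weight_sd, cfg$weight_range)
  height <- .rtruncnorm(n, cfg$height_mean, cfg$height_sd, cfg$height_range)
  for (h in seq_len(n_hips)) {
    s <- subject_of[h]
    head_r <- .rtruncnorm(1L, cfg$head_radius_mean, cfg$head_radius_sd,
                          cfg$head_radius_range)
    base <- hip_geometry(
      head_radius = head_r, clearance = cfg$clearance,
      inclination = stats::rnorm(1L, cfg$inclination_mean, cfg$inclination_sd),
      anteversion = stats::rnorm(1L, cfg$anteversion_mean, cfg$anteversion_sd),
      target_element_size = cfg$target_element_size
    )
    pre_lcea <- .rtruncnorm(1L, cfg$pre_lcea_mean, cfg$pre_lcea_sd,
                            cfg$pre_lcea_range)
    pre_acea <- .rtruncnorm(1L, cfg$pre_acea_mean, cfg$pre_acea_sd,
                            cfg$pre_acea_range)
    pre <- calibrate_coverage(base, pre_lcea, pre_acea,
                              inferior = cfg$inferior_anchor,
                              posterior = cfg$posterior_anchor)
    post_lcea <- .rtruncnorm(1L, cfg$post_lcea_mean, cfg$post_lcea_sd,
                             cfg$post_lcea_range)
    post_acea <- .rtruncnorm(1L, cfg$post_acea_mean, cfg$post_acea_sd,
                             cfg$post_acea_range)
    rot <- .solve_pao_rotation(pre, post_lcea, post_acea)
    rot <- rot + stats::rnorm(3L, 0, cfg$correction_noise_sd)
    rot <- pmin(45, pmax(-45, rot))
    post <- simulate_pao(pre, rot)
    hips[[h]] <- list(
      hip_id = sprintf("H%02d", h),
      subject_id = sprintf("S%02d", s),
      side = if (h > n) "L" else "R",
      sex = sex[s], age = age[s], weight = weight[s], height = height[s],
      acetabular_radius = pre$cup_radius,
      pre_geometry = pre, post_geometry = post,
      pre_measures = radiographic_measures_params(pre),
      post_measures = radiographic_measures_params(post),
      pao_rotation = rot
    )
  }
  structure(hips, class = "hip_cohort")
}

# rotation angles (rx about anterior axis for LCEA, rz about lateral axis
# for ACEA) reaching the target post-op measures; solved by root finding
.solve_pao_rotation <- function(pre, target_lcea, target_acea) {
  rx <- 0; rz <- 0
  for (pass in 1:3) {
    f_rx <- function(v) {
      radiographic_measures_params(simulate_pao(pre, c(v, 0, rz)))$LCEA - target_lcea
    }
    rx <- tryCatch(stats::uniroot(f_rx, c(-44, 44), tol = 1e-2)$root,
                   error = function(e) rx)
    f_rz <- function(v) {
      radiographic_measures_params(simulate_pao(pre, c(rx, 0, v)))$ACEA - target_acea
    }
    rz <- tryCatch(stats::uniroot(f_rz, c(-44, 44), tol = 1e-2)$root,
                   error = function(e) rz)
  }
  c(rx, 0, rz)
}

#' Cohort manifest table
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame, one row per hip, with covariates and the five
#'   radiographic measures pre- and post-operatively.
#' @export
cohort_manifest <- function(cohort) {
  rows <- lapply(cohort, function(h) {
    data.frame(
      hip_id = h$hip_id, subject_id = h$subject_id, side = h$side,
      sex = h$sex, age = h$age, height_m = h$height, weight_kg = h$weight,
      acetabular_radius_mm = h$acetabular_radius,
      LCEA_pre = h$pre_measures$LCEA, AI_pre = h$pre_measures$AI,
      ACEA_pre = h$pre_measures$ACEA, AAA_pre = h$pre_measures$AAA,
      FHEI_pre = h$pre_measures$FHEI,
      LCEA_post = h$post_measures$LCEA, AI_post = h$post_measures$AI,
      ACEA_post = h$post_measures$ACEA, AAA_post = h$post_measures$AAA,
      FHEI_post = h$post_measures$FHEI
    )
  })
  do.call(rbind, rows)
}

#' Write a cohort to disk (PLY meshes + CSV manifest)
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @param seed seed forwarded to the mesh generators.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, seed = 1L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (h in cohort) {
    for (tr in c("pre", "post")) {
      g <- h[[paste0(tr, "_geometry")]]
      cup <- generate_acetabulum(g, seed)
      head <- generate_femoral_head(g, seed)
      write_surface(cup$surface,
                    file.path(dir, sprintf("%s_%s_acetabulum.ply", h$hip_id, tr)))
      write_surface(head$surface,
                    file.path(dir, sprintf("%s_%s_femur.ply", h$hip_id, tr)))
    }
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(cohort_manifest(cohort), path, row.names = FALSE)
  invisible(path)
}
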