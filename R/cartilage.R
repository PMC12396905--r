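#' Parameters of the radial-offset ("healthy") cartilage model
#'
#' Cartilage is recreated from the subchondral surface by offsetting every
#' vertex 1 mm along its radial axis into the joint space, then smoothing
#' the offset surface toward sphericity 5 times with per-vertex moves
#' clamped at 0.05 mm.
#'
#' @param offset radial offset, mm (> 0).
#' @param smoothing_iterations number of sphericity-smoothing passes.
#' @param max_step per-vertex per-iteration clamp, mm.
#' @return object of class `shivanna_params`.
#' @export
shivanna_params <- function(offset = 1.0, smoothing_iterations = 5L,
                            max_step = 0.05) {
  stopifnot(offset > 0, smoothing_iterations >= 0, max_step > 0)
  structure(list(offset = offset,
                 smoothing_iterations = as.integer(smoothing_iterations),
                 max_step = max_step),
            class = "shivanna_params")
}

#' Sphericity smoothing of vertex radii
#'
#' Jacobi-style iteration: each vertex radius moves toward the mean
#' radius of its 1-ring neighbours, the move clamped to `max_step` per
#' iteration; all vertices are updated simultaneously from the previous
#' iterate. Angular coordinates are unchanged. Isolated vertices are left
#' in place with a warning.
#'
#' @param surface a [tri_surface()].
#' @param frame a [spherical_frame()] defining the radial axes.
#' @param iterations number of passes.
#' @param max_step clamp, mm.
#' @return The smoothed `tri_surface`.
#' @export
sphericity_smooth <- function(surface, frame, iterations = 5L,
                              max_step = 0.05) {
  stopifnot(inherits(surface, "tri_surface"), iterations >= 0, max_step > 0)
  v <- surface$vertices
  ctr <- matrix(frame$center, nrow(v), 3, byrow = TRUE)
  d <- v - ctr
  r <- sqrt(rowSums(d^2))
  u <- d / r
  f <- surface$faces
  from <- c(f[, 1L], f[, 2L], f[, 3L], f[, 2L], f[, 3L], f[, 1L])
  to <- c(f[, 2L], f[, 3L], f[, 1L], f[, 1L], f[, 2L], f[, 3L])
  key <- paste(from, to)
  keep <- !duplicated(key)
  from <- from[keep]; to <- to[keep]
  deg <- tabulate(from, nbins = nrow(v))
  if (any(deg == 0L))
    warning("isolated vertices left unchanged by sphericity smoothing")
  for (it in seq_len(iterations)) {
    nb_sum <- rowsum(r[to], from, reorder = TRUE)
    nb_mean <- r
    nb_mean[deg > 0L] <- nb_sum[, 1L] / deg[deg > 0L]
    delta <- pmin(max_step, pmax(-max_step, nb_mean - r))
    r <- r + delta
  }
  surface$vertices <- ctr + u * r
  .refresh_elements(surface)
}

#' Cartilage layer
#'
#' Internal constructor pairing a subchondral surface with its cartilage
#' contact surface (same topology) and per-element thickness.
#' @noRd
.cartilage_layer <- function(subchondral, contact, frame, side) {
  rs <- radial_decomposition(subchondral, frame)$radius
  rc <- radial_decomposition(contact, frame)$radius
  per_vertex <- abs(rs - rc)
  f <- contact$faces
  thickness <- (per_vertex[f[, 1L]] + per_vertex[f[, 2L]] + per_vertex[f[, 3L]]) / 3
  if (any(thickness <= 0)) stop("cartilage layer has non-positive thickness")
  structure(list(subchondral = subchondral, contact = contact,
                 thickness = thickness, frame = frame, side = side),
            class = "cartilage_layer")
}

#' @export
print.cartilage_layer <- function(x, ...) {
  cat(sprintf("cartilage_layer (%s): %d elements, thickness %.3f-%.3f mm\n",
              x$side, length(x$thickness), min(x$thickness), max(x$thickness)))
  invisible(x)
}

#' Radial-offset cartilage with sphericity smoothing
#'
#' Offsets each subchondral vertex `params$offset` mm along its radial
#' axis into the joint space (acetabular side: toward the joint centre;
#' femoral side: away from it), then applies [sphericity_smooth()].
#' Per-element thickness is the mean radial gap between the subchondral
#' and contact surfaces over the element's vertices.
#'
#' @param sub subchondral [tri_surface()].
#' @param frame joint [spherical_frame()] (radial axes).
#' @param params a [shivanna_params()].
#' @param side `"acetabular"` or `"femoral"`.
#' @return A `cartilage_layer`.
#' @export
shivanna_offset <- function(sub, frame, params = shivanna_params(),
                            side = c("acetabular", "femoral")) {
  side <- match.arg(side)
  stopifnot(inherits(sub, "tri_surface"), inherits(params, "shivanna_params"))
  ctr <- matrix(frame$center, nrow(sub$vertices), 3, byrow = TRUE)
  d <- sub$vertices - ctr
  r <- sqrt(rowSums(d^2))
  if (any(r < 1e-12)) stop("vertex coincides with the frame centre")
  if (side == "acetabular" && any(r <= params$offset))
    stop("offset is not smaller than the local radius")
  u <- d / r
  r_new <- if (side == "acetabular") r - params$offset else r + params$offset
  contact <- sub
  contact$vertices <- ctr + u * r_new
  contact <- .refresh_elements(contact)
  if (params$smoothing_iterations > 0L)
    contact <- sphericity_smooth(contact, frame,
                                 params$smoothing_iterations, params$max_step)
  .cartilage_layer(sub, contact, frame, side)
}

#' Fit a biharmonic-spline thickness map
#'
#' Thin-plate (biharmonic) spline interpolation of cartilage thickness
#' samples given in spherical coordinates (polar, azimuth in degrees).
#' Interpolation is exact at the sample sites; evaluation is clamped to a
#' positive floor so interpolated thickness stays physical.
#'
#' @param samples data.frame with columns `polar_deg`, `azimuth_deg`,
#'   `thickness_mm` (at least 3 non-collinear sites, no duplicates).
#' @param floor evaluation floor, mm.
#' @return object of class `thickness_map`; evaluate with
#'   [evaluate_thickness()].
#' @export
fit_thickness_map <- function(samples, floor = 0.2) {
  stopifnot(is.data.frame(samples), floor > 0)
  need <- c("polar_deg", "azimuth_deg", "thickness_mm")
  if (!all(need %in% names(samples)))
    stop("samples must have columns polar_deg, azimuth_deg, thickness_mm")
  x <- samples$polar_deg; y <- samples$azimuth_deg; z <- samples$thickness_mm
  n <- length(x)
  if (n < 3L) stop("need at least 3 thickness samples")
  if (anyDuplicated(cbind(x, y))) stop("duplicate thickness sample sites")
  if (any(z <= 0)) stop("thickness samples must be positive")
  P <- cbind(1, x, y)
  if (qr(P)$rank < 3L) stop("thickness sample sites are collinear")
  K <- .tps_kernel(cbind(x, y), cbind(x, y))
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- c(z, rep(0, 3L))
  sol <- solve(A, rhs)
  structure(list(sites = cbind(x, y), w = sol[seq_len(n)],
                 a = sol[n + 1:3], floor = floor, samples = samples),
            class = "thickness_map")
}

# thin-plate kernel r^2 log r (0 at r = 0)
.tps_kernel <- function(p, q) {
  d2 <- outer(p[, 1L], q[, 1L], "-")^2 + outer(p[, 2L], q[, 2L], "-")^2
  k <- matrix(0, nrow(p), nrow(q))
  pos <- d2 > 0
  k[pos] <- 0.5 * d2[pos] * log(d2[pos])
  k
}

#' Evaluate a thickness map
#'
#' @param map a [fit_thickness_map()] result.
#' @param polar_deg,azimuth_deg query coordinates (degrees).
#' @return thickness in mm, clamped below at the map's floor.
#' @export
evaluate_thickness <- function(map, polar_deg, azimuth_deg) {
  stopifnot(inherits(map, "thickness_map"))
  q <- cbind(polar_deg, azimuth_deg)
  val <- .tps_kernel(q, map$sites) %*% map$w +
    cbind(1, q) %*% map$a
  pmax(map$floor, as.numeric(val))
}

#' Default rim-thickened acetabular thickness map
#'
#' A synthetic 12-site map, about 1.4 mm centrally rising to 2.6 mm
#' toward the lateral rim, emulating the reported pattern of thicker
#' acetabular cartilage at the rim in dysplastic hips. These values are a
#' packaged synthetic default, not measured data; supply your own samples
#' via [fit_thickness_map()] (or a CSV with the same columns) for real
#' mappings.
#'
#' @param floor evaluation floor forwarded to [fit_thickness_map()].
#' @return A `thickness_map`.
#' @export
default_thickness_map <- function(floor = 0.2) {
  samples <- data.frame(
    polar_deg = c(15, 15, 15, 45, 45, 45, 45, 95, 95, 95, 95, 95),
    azimuth_deg = c(0, 120, 240, 0, 90, 180, 270, 0, 45, 90, 180, 270),
    thickness_mm = c(1.4, 1.4, 1.4, 1.7, 1.6, 1.5, 1.5, 2.6, 2.5, 2.3, 1.8, 1.9)
  )
  fit_thickness_map(samples, floor = floor)
}

#' Thickness-map ("dysplastic") acetabular cartilage
#'
#' Offsets each subchondral vertex toward the joint centre by the
#' thickness-map value at its spherical coordinates. Topology is
#' preserved; per-element thickness is the mean radial gap over the
#' element's vertices (identical bookkeeping to [shivanna_offset()], so
#' a constant map reproduces the unsmoothed radial offset exactly).
#'
#' @param sub subchondral [tri_surface()] (acetabular side).
#' @param frame joint [spherical_frame()].
#' @param map a [fit_thickness_map()] result.
#' @return A `cartilage_layer` with side `"acetabular"`.
#' @export
nishii_offset <- function(sub, frame, map = default_thickness_map()) {
  stopifnot(inherits(sub, "tri_surface"), inherits(map, "thickness_map"))
  dec <- radial_decomposition(sub, frame)
  t_v <- evaluate_thickness(map, dec$polar, dec$azimuth)
  if (any(t_v <= 0)) stop("thickness map evaluates to non-positive values")
  if (any(t_v >= dec$radius))
    stop("thickness map exceeds the local subchondral radius")
  ctr <- matrix(frame$center, nrow(sub$vertices), 3, byrow = TRUE)
  u <- (sub$vertices - ctr) / dec$radius
  contact <- sub
  contact$vertices <- ctr + u * (dec$radius - t_v)
  contact <- .refresh_elements(contact)
  .cartilage_layer(sub, contact, frame, "acetabular")
}
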