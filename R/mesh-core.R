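#' Triangulated open surface
#'
#' Construct a `tri_surface`, the geometric carrier used throughout the
#' package for subchondral and cartilage contact surfaces. Per-element
#' area, centroid and unit normal are computed at construction time and
#' degenerate (zero-area) faces are dropped. All coordinates are in mm,
#' areas in mm^2.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `tri_surface` with components `vertices`,
#'   `faces`, `element_area`, `element_centroid`, `element_normal` and
#'   `vertex_adjacency` (list of neighbouring vertex indices).
#' @export
tri_surface <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix")
  if (nrow(vertices) < 3L || nrow(faces) < 1L)
    stop("mesh is empty or too small to form a surface")
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")

  props <- .face_properties(vertices, faces)
  keep <- props$area > 1e-12
  if (!any(keep)) stop("mesh contains only degenerate faces")
  faces <- faces[keep, , drop = FALSE]

  s <- structure(
    list(vertices = vertices, faces = faces),
    class = "tri_surface"
  )
  s <- .refresh_elements(s)
  s$vertex_adjacency <- .vertex_adjacency(nrow(vertices), faces)
  s
}

# per-face area/centroid/normal; normal from the right-hand winding rule
.face_properties <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- c3 - a
  cr <- cbind(
    e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
    e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
    e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  )
  nrm2 <- sqrt(rowSums(cr^2))
  area <- nrm2 / 2
  normal <- cr / ifelse(nrm2 > 0, nrm2, 1)
  list(area = area, centroid = (a + b + c3) / 3, normal = normal)
}

.refresh_elements <- function(s) {
  props <- .face_properties(s$vertices, s$faces)
  s$element_area <- props$area
  s$element_centroid <- props$centroid
  s$element_normal <- props$normal
  s
}

.vertex_adjacency <- function(n_vertices, faces) {
  # undirected 1-ring neighbourhoods from face edges
  from <- c(faces[, 1L], faces[, 2L], faces[, 3L],
            faces[, 2L], faces[, 3L], faces[, 1L])
  to <- c(faces[, 2L], faces[, 3L], faces[, 1L],
          faces[, 1L], faces[, 2L], faces[, 3L])
  adj <- split(to, factor(from, levels = seq_len(n_vertices)))
  lapply(adj, function(v) sort(unique(v)))
}

#' @export
print.tri_surface <- function(x, ...) {
  cat(sprintf(
    "tri_surface: %d vertices, %d faces, total area %.3f mm^2\n",
    nrow(x$vertices), nrow(x$faces), sum(x$element_area)
  ))
  invisible(x)
}

#' Per-element geometric properties
#'
#' @param surface a [tri_surface()].
#' @return data.frame with columns `area` (mm^2), `cx`, `cy`, `cz`
#'   (centroid, mm) and `nx`, `ny`, `nz` (unit normal).
#' @export
element_properties <- function(surface) {
  stopifnot(inherits(surface, "tri_surface"))
  data.frame(
    area = surface$element_area,
    cx = surface$element_centroid[, 1L],
    cy = surface$element_centroid[, 2L],
    cz = surface$element_centroid[, 3L],
    nx = surface$element_normal[, 1L],
    ny = surface$element_normal[, 2L],
    nz = surface$element_normal[, 3L]
  )
}

#' Orient element normals relative to a centre point
#'
#' Flips the winding of any face whose normal does not point in the
#' requested direction relative to `center`, so that sphere-like patches
#' end up with a consistent orientation: `"toward"` for an acetabular
#' surface (normals into the joint space, toward the head centre),
#' `"away"` for a femoral surface.
#'
#' @param surface a [tri_surface()].
#' @param center numeric length-3, reference point (mm).
#' @param direction `"toward"` or `"away"`.
#' @return The reoriented `tri_surface`.
#' @export
orient_surface <- function(surface, center, direction = c("toward", "away")) {
  stopifnot(inherits(surface, "tri_surface"))
  direction <- match.arg(direction)
  center <- as.numeric(center)
  radial <- surface$element_centroid - matrix(center, nrow(surface$faces), 3, byrow = TRUE)
  d <- rowSums(surface$element_normal * radial)
  if (any(abs(d) < 1e-12 * sqrt(rowSums(radial^2))))
    stop("cannot orient: some faces are radial (normal perpendicular to the centre ray)")
  want_neg <- direction == "toward"
  flip <- if (want_neg) d > 0 else d < 0
  if (any(flip)) {
    surface$faces[flip, c(2L, 3L)] <- surface$faces[flip, c(3L, 2L)]
    surface <- .refresh_elements(surface)
  }
  surface
}

#' Midpoint 1-to-4 subdivision
#'
#' Splits every face into four by edge midpoints. Total area is conserved
#' exactly (used as a refinement primitive and a geometric sanity check).
#'
#' @param surface a [tri_surface()].
#' @param project_radius optional; if given, new and old vertices are
#'   projected onto the sphere of this radius about `project_center`.
#' @param project_center centre for the projection (default origin).
#' @return The subdivided `tri_surface`.
#' @export
subdivide_surface <- function(surface, project_radius = NULL,
                              project_center = c(0, 0, 0)) {
  stopifnot(inherits(surface, "tri_surface"))
  v <- surface$vertices
  f <- surface$faces
  # unique edge midpoints
  edges <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(edges[, 1L], edges[, 2L]),
                pmax(edges[, 1L], edges[, 2L]), sep = "_")
  uidx <- !duplicated(ekey)
  uedges <- edges[uidx, , drop = FALSE]
  mid <- (v[uedges[, 1L], , drop = FALSE] + v[uedges[, 2L], , drop = FALSE]) / 2
  mid_id <- nrow(v) + match(ekey, ekey[uidx])
  m <- nrow(f)
  ab <- mid_id[seq_len(m)]
  bc <- mid_id[m + seq_len(m)]
  ca <- mid_id[2L * m + seq_len(m)]
  newf <- rbind(
    cbind(f[, 1L], ab, ca),
    cbind(ab, f[, 2L], bc),
    cbind(ca, bc, f[, 3L]),
    cbind(ab, bc, ca)
  )
  newv <- rbind(v, mid)
  if (!is.null(project_radius)) {
    ctr <- matrix(as.numeric(project_center), nrow(newv), 3, byrow = TRUE)
    d <- newv - ctr
    r <- sqrt(rowSums(d^2))
    newv <- ctr + d * (project_radius / r)
  }
  tri_surface(newv, newf)
}

#' Icosphere
#'
#' Geodesic sphere obtained by subdividing an icosahedron `subdivisions`
#' times and projecting onto the sphere; 20 * 4^k faces.
#'
#' @param radius sphere radius, mm.
#' @param subdivisions number of 1-to-4 refinement passes.
#' @param center sphere centre (mm).
#' @return A `tri_surface`.
#' @export
icosphere <- function(radius = 1, subdivisions = 2L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  s <- tri_surface(v, f)
  for (i in seq_len(subdivisions))
    s <- subdivide_surface(s, project_radius = 1)
  ctr <- matrix(as.numeric(center), nrow(s$vertices), 3, byrow = TRUE)
  s$vertices <- s$vertices * radius + ctr
  s <- .refresh_elements(s)
  orient_surface(s, center, "away")
}

#' Spherical reference frame
#'
#' A centre point plus a right-handed orthonormal triad. The polar angle
#' of [radial_decomposition()] is measured from the third axis, azimuth
#' from the first toward the second.
#'
#' @param center 3-vector, mm.
#' @param axes 3 x 3 matrix whose columns are the frame axes.
#' @return An object of class `spherical_frame`.
#' @export
spherical_frame <- function(center, axes = diag(3)) {
  center <- as.numeric(center)
  axes <- as.matrix(axes)
  stopifnot(length(center) == 3L, all(dim(axes) == c(3L, 3L)))
  g <- crossprod(axes)
  if (max(abs(g - diag(3))) > 1e-9) stop("frame axes are not orthonormal")
  if (det(axes) < 0) stop("frame axes are not right-handed")
  structure(list(center = center, axes = axes), class = "spherical_frame")
}

#' Radial (spherical-coordinate) decomposition
#'
#' Expresses vertices in spherical coordinates about a frame: radius (mm),
#' polar angle in degrees from the frame's third axis (0..180), azimuth in
#' degrees from the first axis toward the second (-180..180).
#'
#' @param x a `tri_surface` or an n x 3 coordinate matrix.
#' @param frame a [spherical_frame()].
#' @return data.frame with columns `radius`, `polar`, `azimuth`.
#' @export
radial_decomposition <- function(x, frame) {
  stopifnot(inherits(frame, "spherical_frame"))
  v <- if (inherits(x, "tri_surface")) x$vertices else as.matrix(x)
  local <- (v - matrix(frame$center, nrow(v), 3, byrow = TRUE)) %*% frame$axes
  r <- sqrt(rowSums(local^2))
  if (any(r < 1e-12)) stop("vertex coincides with the frame centre")
  polar <- acos(pmin(1, pmax(-1, local[, 3L] / r))) * 180 / pi
  azimuth <- atan2(local[, 2L], local[, 1L]) * 180 / pi
  azimuth[azimuth >= 180] <- azimuth[azimuth >= 180] - 360
  data.frame(radius = r, polar = polar, azimuth = azimuth)
}

#' Inverse of [radial_decomposition()]
#'
#' @param radius,polar,azimuth spherical coordinates (mm, degrees).
#' @param frame a [spherical_frame()].
#' @return n x 3 matrix of Cartesian coordinates in the world frame.
#' @export
spherical_to_cartesian <- function(radius, polar, azimuth, frame) {
  stopifnot(inherits(frame, "spherical_frame"))
  th <- polar * pi / 180
  ph <- azimuth * pi / 180
  local <- cbind(
    radius * sin(th) * cos(ph),
    radius * sin(th) * sin(ph),
    radius * cos(th)
  )
  local %*% t(frame$axes) +
    matrix(frame$center, length(radius), 3, byrow = TRUE)
}

# rotation matrices about the frame axes, angle in degrees
.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
.rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-15) stop("cannot normalize a zero vector")
  v / n
}

# orthonormal basis completing a unit axis e3 -> columns (e1, e2, e3)
.complete_basis <- function(e3) {
  e3 <- .normalize(e3)
  seed <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- .normalize(seed - sum(seed * e3) * e3)
  e2 <- c(
    e3[2L] * e1[3L] - e3[3L] * e1[2L],
    e3[3L] * e1[1L] - e3[1L] * e1[3L],
    e3[1L] * e1[2L] - e3[2L] * e1[1L]
  )
  cbind(e1, e2, e3)
}
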