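#' Read a triangulated surface mesh
#'
#' Reads PLY (ascii or binary little-endian), STL (ascii or binary) or
#' OBJ (vertices + triangular faces) files into a [tri_surface()].
#' Coordinates are assumed to be in mm.
#'
#' @param path file path.
#' @param format `"ply"`, `"stl"` or `"obj"`; guessed from the file
#'   extension when missing.
#' @return A [tri_surface()].
#' @export
read_surface <- function(path, format = c("auto", "ply", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("ply", "stl", "obj"))
      stop("cannot guess mesh format from extension '", ext, "'")
    format <- ext
  }
  out <- switch(format,
    ply = .read_ply(path),
    stl = .read_stl(path),
    obj = .read_obj(path)
  )
  tri_surface(out$vertices, out$faces)
}

#' Write a triangulated surface mesh
#'
#' @param surface a [tri_surface()].
#' @param path output path.
#' @param format `"ply"`, `"stl"` or `"obj"` (guessed from extension).
#' @param binary write the binary variant (PLY binary little-endian or
#'   binary STL); ascii otherwise.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path,
                          format = c("auto", "ply", "stl", "obj"),
                          binary = FALSE) {
  stopifnot(inherits(surface, "tri_surface"))
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    ply = .write_ply(surface, path, binary),
    stl = .write_stl(surface, path, binary),
    obj = .write_obj(surface, path),
    stop("unsupported mesh format '", format, "'")
  )
  invisible(path)
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (length(magic) == 0L || trimws(magic) != "ply")
    stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()     # list of (name, count, properties)
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated PLY header")
    toks <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(toks) == 0L || toks[1L] == "comment") next
    if (toks[1L] == "format") {
      fmt <- toks[2L]
    } else if (toks[1L] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2L], count = as.integer(toks[3L]),
                  props = list())
    } else if (toks[1L] == "property") {
      cur$props[[length(cur$props) + 1L]] <- toks[-1L]
    } else if (toks[1L] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (is.null(fmt) || is.null(elements$vertex) || is.null(elements$face))
    stop("PLY header lacks format/vertex/face declarations")
  nv <- elements$vertex$count
  nf <- elements$face$count
  if (is.na(nv) || is.na(nf) || nv < 1L || nf < 1L)
    stop("PLY mesh is empty")
  vprops <- elements$vertex$props
  vnames <- vapply(vprops, function(p) p[length(p)], "")
  ixyz <- match(c("x", "y", "z"), vnames)
  if (any(is.na(ixyz))) stop("PLY vertex element lacks x/y/z properties")

  if (fmt == "ascii") {
    rest <- readLines(con, warn = FALSE)
    rest <- rest[nzchar(trimws(rest))]
    if (length(rest) < nv + nf) stop("truncated PLY body")
    vtok <- strsplit(trimws(rest[seq_len(nv)]), "\\s+")
    if (any(vapply(vtok, length, 0L) < max(ixyz)))
      stop("truncated PLY vertex record")
    vm <- t(vapply(vtok, function(t) as.numeric(t[ixyz]), numeric(3L)))
    ftok <- strsplit(trimws(rest[nv + seq_len(nf)]), "\\s+")
    fm <- t(vapply(ftok, function(t) {
      n <- as.integer(t[1L])
      if (is.na(n) || n != 3L) stop("only triangular PLY faces supported")
      as.integer(t[2:4])
    }, integer(3L)))
  } else if (fmt == "binary_little_endian") {
    sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
               short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
               int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
               float = 4L, float32 = 4L, double = 8L, float64 = 8L)
    ptypes <- vapply(vprops, function(p) p[1L], "")
    if (any(ptypes == "list")) stop("list-typed PLY vertex properties unsupported")
    psize <- sizes[ptypes]
    if (any(is.na(psize))) stop("unknown PLY property type")
    vm <- matrix(NA_real_, nv, 3L)
    for (i in seq_len(nv)) {
      for (j in seq_along(vprops)) {
        val <- if (ptypes[j] %in% c("float", "float32", "double", "float64")) {
          readBin(con, "double", 1L, size = psize[j], endian = "little")
        } else {
          readBin(con, "integer", 1L, size = psize[j], endian = "little")
        }
        if (length(val) == 0L) stop("truncated PLY vertex data")
        k <- match(j, ixyz)
        if (!is.na(k)) vm[i, k] <- val
      }
    }
    fp <- elements$face$props[[1L]]
    if (fp[1L] != "list") stop("PLY face element must be a list property")
    csize <- sizes[fp[2L]]; isize <- sizes[fp[3L]]
    fm <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      n <- readBin(con, "integer", 1L, size = csize, endian = "little")
      if (length(n) == 0L) stop("truncated PLY face data")
      if (n != 3L) stop("only triangular PLY faces supported")
      idx <- readBin(con, "integer", 3L, size = isize, endian = "little")
      if (length(idx) < 3L) stop("truncated PLY face data")
      fm[i, ] <- idx
    }
  } else {
    stop("unsupported PLY format: ", fmt)
  }
  list(vertices = vm, faces = fm + 1L)
}

.write_ply <- function(surface, path, binary) {
  v <- surface$vertices
  f <- surface$faces - 1L
  hdr <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(v)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  }
}

.read_stl <- function(path) {
  # sniff ascii vs binary: ascii files start with "solid" and contain "facet"
  head_raw <- readBin(path, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0L)])
  is_ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  tri <- if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
      stop("truncated or empty ascii STL")
    coords <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                       function(t) as.numeric(t[2:4]), numeric(3L)))
    if (any(!is.finite(coords))) stop("unparsable ascii STL vertex")
    coords
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    nf <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(nf) == 0L || nf < 1L) stop("empty binary STL")
    coords <- matrix(NA_real_, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      rec <- readBin(con, "double", 12L, size = 4L, endian = "little")
      if (length(rec) < 12L) stop("truncated binary STL")
      invisible(readBin(con, "raw", 2L))
      coords[3L * i - 2L, ] <- rec[4:6]
      coords[3L * i - 1L, ] <- rec[7:9]
      coords[3L * i, ] <- rec[10:12]
    }
    coords
  }
  # weld coincident vertices (exact match on printed coordinates)
  key <- apply(round(tri, 9L), 1L, paste, collapse = "_")
  uid <- !duplicated(key)
  verts <- tri[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

.write_stl <- function(surface, path, binary) {
  v <- surface$vertices
  f <- surface$faces
  n <- surface$element_normal
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      rec <- c(n[i, ], t(v[f[i, ], ]))
      writeBin(as.numeric(rec), con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid surface", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1L], n[i, 2L], n[i, 3L]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g",
                           p[1L], p[2L], p[3L]), con)
      }
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid surface", con)
  }
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(flines) == 0L)
    stop("OBJ file has no vertices or faces")
  vm <- t(vapply(strsplit(trimws(vlines), "\\s+"),
                 function(t) as.numeric(t[2:4]), numeric(3L)))
  fm <- t(vapply(strsplit(trimws(flines), "\\s+"), function(t) {
    t <- t[-1L]
    if (length(t) != 3L) stop("only triangular OBJ faces supported")
    as.integer(vapply(strsplit(t, "/"), `[[`, "", 1L))
  }, integer(3L)))
  if (any(!is.finite(vm))) stop("unparsable OBJ vertex")
  list(vertices = vm, faces = fm)
}

.write_obj <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- surface$vertices
  f <- surface$faces
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
}
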