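#' Triangulated surface meshes
#'
#' A `surf_mesh` is the spatial substrate for all vertex-wise statistics:
#' a triangulated surface with vertex coordinates in millimetres, triangle
#' indices, and a logical cortex mask marking the vertices that enter the
#' analysis (the unmasked region stands in for the medial wall, where
#' cortical measurements are undefined).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param cortex_mask logical vector, one entry per vertex; `TRUE` vertices
#'   are analysed. Defaults to all `TRUE`.
#' @return An object of class `surf_mesh`.
#' @export
surf_mesh <- function(vertices, faces, cortex_mask = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L) stop("faces must be triangles (3 columns)")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range [1, n_vertices]")
  }
  if (is.null(cortex_mask)) cortex_mask <- rep(TRUE, nrow(vertices))
  cortex_mask <- as.logical(cortex_mask)
  if (length(cortex_mask) != nrow(vertices)) {
    stop("cortex_mask length must equal the vertex count")
  }
  structure(
    list(vertices = vertices, faces = faces, cortex_mask = cortex_mask),
    class = "surf_mesh"
  )
}

#' @export
print.surf_mesh <- function(x, ...) {
  cat(sprintf(
    "<surf_mesh> %d vertices, %d triangles, %d masked-in (cortex)\n",
    n_vertices(x), nrow(x$faces), sum(x$cortex_mask)
  ))
  invisible(x)
}

#' @rdname surf_mesh
#' @param mesh a `surf_mesh`.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' Unique mesh edges
#'
#' @param mesh a `surf_mesh`.
#' @return Integer matrix with columns `i`, `j` (`i < j`), one row per
#'   undirected edge.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  colnames(e) <- c("i", "j")
  e
}

#' Sparse vertex adjacency matrix
#'
#' @param mesh a `surf_mesh`.
#' @return A symmetric sparse 0/1 `Matrix` of vertex adjacency.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- n_vertices(mesh)
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
    x = 1, dims = c(n, n)
  )
}

#' Triangle and vertex areas
#'
#' Triangle areas are half the cross-product norm; each vertex receives a
#' third of the area of every triangle incident to it (barycentric lumping),
#' so vertex areas sum to the total surface area.
#'
#' @param mesh a `surf_mesh`.
#' @return `triangle_areas()`: numeric vector, mm^2 per triangle.
#' @export
triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname triangle_areas
#' @return `vertex_areas()`: numeric vector, mm^2 per vertex.
#' @export
vertex_areas <- function(mesh) {
  ta <- triangle_areas(mesh)
  n <- n_vertices(mesh)
  va <- numeric(n)
  for (k in 1:3) {
    s <- tapply(ta, mesh$faces[, k], sum)
    idx <- as.integer(names(s))
    va[idx] <- va[idx] + s
  }
  va / 3
}

#' Edge lengths in mm
#' @param mesh a `surf_mesh`.
#' @param edges optional edge matrix from [mesh_edges()].
#' @return numeric vector of Euclidean edge lengths.
#' @export
edge_lengths <- function(mesh, edges = mesh_edges(mesh)) {
  d <- mesh$vertices[edges[, 1], , drop = FALSE] -
    mesh$vertices[edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

# icosahedron with unit circumradius
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

# one loop-style 1:4 subdivision, midpoints projected to the unit sphere
subdivide_sphere <- function(v, f) {
  key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  ek <- key(e[, 1], e[, 2])
  uk <- unique(ek)
  mid_id <- stats::setNames(seq_along(uk) + nrow(v), uk)
  ue <- e[!duplicated(ek), , drop = FALSE]
  mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
  mids <- mids / sqrt(rowSums(mids^2))
  m12 <- mid_id[key(f[, 1], f[, 2])]
  m23 <- mid_id[key(f[, 2], f[, 3])]
  m13 <- mid_id[key(f[, 1], f[, 3])]
  newf <- rbind(
    cbind(f[, 1], m12, m13),
    cbind(f[, 2], m23, m12),
    cbind(f[, 3], m13, m23),
    cbind(m12, m23, m13)
  )
  list(vertices = rbind(v, mids), faces = unname(newf))
}

#' Spherical cortical-surface stand-in
#'
#' Builds an icosphere (recursively subdivided icosahedron projected to a
#' sphere) with `10 * 4^subdivisions + 2` vertices, scaled to the requested
#' radius. A small polar cap around the +z pole is masked out of the cortex
#' mask as a medial-wall stand-in, so downstream stages always exercise the
#' masked-analysis path.
#'
#' @param subdivisions integer >= 0; number of 1:4 triangle subdivisions.
#' @param radius sphere radius in mm (default 80, a brain-scale hemisphere).
#' @param cap_degrees angular radius of the masked polar cap, degrees
#'   (default 20; 0 disables masking).
#' @return A `surf_mesh`.
#' @examples
#' m <- make_mesh(2)
#' n_vertices(m) # 162
#' @export
make_mesh <- function(subdivisions = 3, radius = 80, cap_degrees = 20) {
  stopifnot(subdivisions >= 0, radius > 0, cap_degrees >= 0)
  s <- icosahedron()
  if (subdivisions > 0) {
    for (k in seq_len(subdivisions)) s <- subdivide_sphere(s$vertices, s$faces)
  }
  v <- s$vertices * radius
  # polar angle from +z; cap of cap_degrees is masked out
  polar <- acos(pmin(1, pmax(-1, s$vertices[, 3])))
  mask <- polar > cap_degrees * pi / 180
  surf_mesh(v, s$faces, mask)
}

#' Read and write surface meshes
#'
#' Supported dialects: ASCII `off` (vertex/face counts then coordinates and
#' polygon lines), ASCII `ply` (element/property header), and `fs-ascii`
#' (FreeSurfer-style .asc: a comment line, `nv nf`, vertex lines `x y z 0`,
#' face lines `i j k 0` with 0-based indices). All on-disk face indices are
#' 0-based; in-memory `surf_mesh` faces are 1-based.
#'
#' @param path file path.
#' @param dialect one of `"off"`, `"ply"`, `"fs-ascii"`; default guessed
#'   from the file extension (.off, .ply, .asc).
#' @return `read_mesh()`: a `surf_mesh` (cortex mask all-`TRUE`; masks are
#'   carried separately in vertex-map files).
#' @export
read_mesh <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("mesh file not found: ", path)
  dialect <- dialect %||% guess_mesh_dialect(path)
  lines <- readLines(path, warn = FALSE)
  switch(dialect,
    "off" = parse_off(lines, path),
    "ply" = parse_ply(lines, path),
    "fs-ascii" = parse_fs_ascii(lines, path),
    stop("unknown mesh dialect: ", dialect)
  )
}

guess_mesh_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "off" = "off", "ply" = "ply", "asc" = "fs-ascii",
    stop("cannot guess mesh dialect from extension '.", ext, "'")
  )
}

strip_blank <- function(lines) {
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

num_fields <- function(line, path, lineno) {
  x <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (anyNA(x)) stop(sprintf("%s: cannot parse line %d: '%s'", path, lineno, line))
  x
}

parse_off <- function(lines, path) {
  s <- strip_blank(lines)
  ln <- s$lines
  no <- s$lineno
  i <- 1
  if (toupper(trimws(ln[i])) == "OFF") i <- i + 1
  cnt <- num_fields(ln[i], path, no[i])
  if (length(cnt) < 2) stop(path, ": OFF count line needs 'nv nf [ne]'")
  nv <- cnt[1]; nf <- cnt[2]
  if (length(ln) < i + nv + nf) stop(path, ": truncated OFF file")
  vl <- vapply(seq_len(nv), function(k) num_fields(ln[i + k], path, no[i + k])[1:3],
               numeric(3))
  v <- t(vl)
  f <- matrix(0L, nf, 3)
  for (k in seq_len(nf)) {
    x <- num_fields(ln[i + nv + k], path, no[i + nv + k])
    if (x[1] != 3) {
      stop(sprintf("%s: non-triangular face (%d vertices) at line %d",
                   path, x[1], no[i + nv + k]))
    }
    f[k, ] <- as.integer(x[2:4]) + 1L
  }
  surf_mesh(v, f)
}

parse_ply <- function(lines, path) {
  if (trimws(lines[1]) != "ply") stop(path, ": missing 'ply' magic on line 1")
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop(path, ": no end_header")
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("^format\\s+ascii", hdr))) stop(path, ": only ascii PLY supported")
  ev <- regmatches(hdr, regexec("^element\\s+vertex\\s+(\\d+)", hdr))
  ef <- regmatches(hdr, regexec("^element\\s+face\\s+(\\d+)", hdr))
  nv <- as.integer(unlist(lapply(ev, `[`, 2)))
  nf <- as.integer(unlist(lapply(ef, `[`, 2)))
  nv <- nv[!is.na(nv)][1]; nf <- nf[!is.na(nf)][1]
  if (is.na(nv) || is.na(nf)) stop(path, ": PLY header lacks vertex/face elements")
  body <- lines[(hdr_end + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop(path, ": truncated PLY body")
  v <- t(vapply(seq_len(nv), function(k) num_fields(body[k], path, hdr_end + k)[1:3],
                numeric(3)))
  f <- matrix(0L, nf, 3)
  for (k in seq_len(nf)) {
    x <- num_fields(body[nv + k], path, hdr_end + nv + k)
    if (x[1] != 3) {
      stop(sprintf("%s: non-triangular face (%d vertices) in PLY body line %d",
                   path, x[1], nv + k))
    }
    f[k, ] <- as.integer(x[2:4]) + 1L
  }
  surf_mesh(v, f)
}

parse_fs_ascii <- function(lines, path) {
  s <- strip_blank(lines)
  ln <- s$lines; no <- s$lineno
  cnt <- num_fields(ln[1], path, no[1])
  nv <- cnt[1]; nf <- cnt[2]
  if (length(ln) < 1 + nv + nf) stop(path, ": truncated fs-ascii file")
  v <- t(vapply(seq_len(nv), function(k) num_fields(ln[1 + k], path, no[1 + k])[1:3],
                numeric(3)))
  f <- matrix(0L, nf, 3)
  for (k in seq_len(nf)) {
    x <- num_fields(ln[1 + nv + k], path, no[1 + nv + k])
    f[k, ] <- as.integer(x[1:3]) + 1L
  }
  surf_mesh(v, f)
}

#' @rdname read_mesh
#' @param mesh a `surf_mesh` to write.
#' @export
write_mesh <- function(mesh, path, dialect = NULL) {
  dialect <- dialect %||% guess_mesh_dialect(path)
  v <- mesh$vertices
  f0 <- mesh$faces - 1L
  out <- switch(dialect,
    "off" = c(
      "OFF",
      sprintf("%d %d 0", nrow(v), nrow(f0)),
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
    ),
    "ply" = c(
      "ply", "format ascii 1.0",
      sprintf("element vertex %d", nrow(v)),
      "property float x", "property float y", "property float z",
      sprintf("element face %d", nrow(f0)),
      "property list uchar int vertex_indices", "end_header",
      sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
      sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])
    ),
    "fs-ascii" = c(
      "#!ascii surface",
      sprintf("%d %d", nrow(v), nrow(f0)),
      sprintf("%.9g %.9g %.9g 0", v[, 1], v[, 2], v[, 3]),
      sprintf("%d %d %d 0", f0[, 1], f0[, 2], f0[, 3])
    ),
    stop("unknown mesh dialect: ", dialect)
  )
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
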