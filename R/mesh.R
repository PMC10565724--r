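#' Isosurface triangle mesh of a field
#'
#' Marching-tetrahedra mesh of the `level` isosurface (default the cell
#' membrane rho = 0.5), with triangles oriented so normals point outward
#' (away from the high side of the field). Vertices are world coordinates
#' in um.
#'
#' @param f 3D array.
#' @param grid grid or spacing.
#' @param level isosurface level (default 0.5).
#' @return A `pf_mesh`: `vertices` (n x 3), `triangles` (m x 3, 1-based).
#' @export
isosurface_mesh <- function(f, grid, level = 0.5) {
  check_field(f)
  if (!any(f > level) || all(f > level)) {
    stop("no isosurface at this level")
  }
  m <- cpp_isosurface(f, level, as_spacing(grid))
  structure(list(vertices = m$vertices, triangles = m$triangles),
            class = "pf_mesh")
}

#' @export
print.pf_mesh <- function(x, ...) {
  cat(sprintf("<pf_mesh %d triangles, area %.1f um^2>\n",
              nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

#' Total area of a triangle mesh
#' @param mesh a `pf_mesh`.
#' @return Scalar area (um^2).
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a closed oriented mesh
#'
#' Divergence-theorem volume `sum (a . (b x c)) / 6` over triangles with
#' outward orientation (as produced by [isosurface_mesh()]).
#'
#' @param mesh a `pf_mesh`.
#' @return Scalar volume (um^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  abs(sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6)
}

#' Merge coincident mesh vertices
#'
#' Welds vertices that agree to `digits` decimal places, re-indexing the
#' triangles. Needed for topological checks (Euler characteristic) on the
#' triangle-soup output of the mesher.
#'
#' @param mesh a `pf_mesh`.
#' @param digits rounding used for the weld (default 6).
#' @return A `pf_mesh` with unique vertices.
#' @export
merge_mesh_vertices <- function(mesh, digits = 6) {
  v <- round(mesh$vertices, digits)
  key <- paste(v[, 1], v[, 2], v[, 3], sep = "|")
  uk <- !duplicated(key)
  map <- match(key, key[uk])
  structure(list(vertices = mesh$vertices[uk, , drop = FALSE],
                 triangles = matrix(map[mesh$triangles],
                                    ncol = 3)),
            class = "pf_mesh")
}

#' Membrane curvature map on the cell surface
#'
#' Builds the rho = 0.5 isosurface mesh and attaches the local membrane
#' curvature `c` (the same field entering the membrane-tension factor),
#' trilinearly interpolated to each vertex.
#'
#' @param rho cell field.
#' @param grid grid or spacing.
#' @param eps_norm,grad_min passed to [interface_curvature()].
#' @return A `pf_mesh` with an extra `curvature` vector (per vertex).
#' @export
curvature_map_mesh <- function(rho, grid, eps_norm = 1e-8, grad_min = 1e-6) {
  h <- as_spacing(grid)
  mesh <- isosurface_mesh(rho, h, level = 0.5)
  cf <- interface_curvature(rho, h, eps_norm, grad_min)
  mesh$curvature <- as.numeric(cpp_trilinear(cf, mesh$vertices, h))
  mesh
}

#' Export a mesh (or a field isosurface) as binary STL
#'
#' Writes a binary STL file with vertex coordinates in um world
#' coordinates. Accepts either a `pf_mesh` or a rho field (meshed at
#' `level`). The write is atomic (temp file + rename).
#'
#' @param x a `pf_mesh` or a 3D array.
#' @param file output path.
#' @param grid grid or spacing (required when `x` is an array).
#' @param level isosurface level for arrays (default 0.5).
#' @return Invisibly, the number of triangles written.
#' @export
export_stl <- function(x, file, grid = NULL, level = 0.5) {
  if (is.array(x)) {
    if (is.null(grid)) stop("grid is required when exporting a field")
    x <- isosurface_mesh(x, grid, level)
  }
  v <- x$vertices; tr <- x$triangles
  n <- nrow(tr)
  tmp <- paste0(file, ".tmp")
  con <- file(tmp, "wb")
  on.exit({ if (!is.null(con)) close(con) }, add = TRUE)
  hdr <- charToRaw(sprintf("%-80s", "phasecell binary STL"))[1:80]
  writeBin(hdr, con)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  c3 <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.eps)
  rec <- rbind(nx / nn, ny / nn, nz / nn, t(a), t(b), t(c3))
  for (q in seq_len(n)) {
    writeBin(as.numeric(rec[, q]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  close(con); con <- NULL
  file.rename(tmp, file)
  invisible(n)
}

#' Read a binary STL file
#'
#' @param file path to a binary STL.
#' @return A `pf_mesh` (triangle soup: 3 vertices per triangle).
#' @export
read_stl <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con), add = TRUE)
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  verts <- matrix(NA_real_, 3 * n, 3)
  for (q in seq_len(n)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    readBin(con, "integer", n = 1, size = 2, endian = "little")
    verts[3 * q - 2, ] <- rec[4:6]
    verts[3 * q - 1, ] <- rec[7:9]
    verts[3 * q, ] <- rec[10:12]
  }
  structure(list(vertices = verts,
                 triangles = matrix(seq_len(3 * n), ncol = 3, byrow = TRUE)),
            class = "pf_mesh")
}
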