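#' Lattice geometry for all fields
#'
#' A grid is a regular voxel lattice with isotropic spacing and zero-flux
#' (mirror) boundary conditions on every face. One length unit corresponds to
#' 1 micrometre; the default spacing of 0.5 matches the discretization used
#' for the cell model, while substrates are built at spacing 1 and
#' interpolated.
#'
#' Voxel centres sit at world coordinate `(index - 1 + 0.5) * spacing` along
#' each axis (1-based R indexing), so the physical extent per axis is
#' `shape[i] * spacing`.
#'
#' @param shape integer triple, voxels per axis (each at least 8).
#' @param spacing voxel edge length in micrometres (> 0).
#' @return An object of class `pf_grid` with elements `shape`, `spacing`.
#' @examples
#' g <- grid_spec(c(32, 32, 32), spacing = 1)
#' @export
grid_spec <- function(shape, spacing = 0.5) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 8)) {
    stop("shape must be an integer triple with every entry >= 8")
  }
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0) {
    stop("spacing must be a positive scalar")
  }
  structure(list(shape = shape, spacing = spacing), class = "pf_grid")
}

#' @export
print.pf_grid <- function(x, ...) {
  cat(sprintf("<pf_grid %d x %d x %d, spacing %g um (extent %g x %g x %g um)>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$shape[1] * x$spacing, x$shape[2] * x$spacing,
              x$shape[3] * x$spacing))
  invisible(x)
}

#' Allocate a scalar field on a grid
#'
#' @param grid a [grid_spec()].
#' @param fill fill value (default 0).
#' @return A 3D numeric array of dimension `grid$shape`.
#' @export
field_array <- function(grid, fill = 0) {
  array(fill, dim = grid$shape)
}

# Accept either a pf_grid or a bare spacing where only spacing matters.
as_spacing <- function(grid) {
  if (inherits(grid, "pf_grid")) return(grid$spacing)
  if (is.numeric(grid) && length(grid) == 1 && grid > 0) return(grid)
  stop("expected a pf_grid or a positive spacing scalar")
}

check_field <- function(f, name = "field") {
  if (!is.array(f) || length(dim(f)) != 3) {
    stop(name, " must be a 3D array")
  }
  invisible(f)
}

# World coordinates of voxel centres along each axis.
axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing
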