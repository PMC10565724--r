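#' Relax a binary solid mask into a diffuse interaction field
#'
#' The substrate location field Phi and the wider sensing field Psi are both
#' obtained by briefly diffusing the binary solid mask on its native
#' spacing-1 lattice: Phi with `D_phi = 0.5` for a total time of 0.15
#' (3 steps of 0.05), Psi with `D_psi = 4` for a total time of 0.25
#' (5 steps of 0.05). The total diffusion time is what sets the interface
#' width, and it is integrated with an internal substep that respects the
#' explicit stability bound. Psi's wider kernel makes its interface extend
#' beyond Phi's, letting an approaching cell sense a surface before contact.
#'
#' @param mask binary (0/1) 3D array at spacing 1.
#' @param which `"phi"` or `"psi"`.
#' @param D_phi,D_psi relaxation diffusivities (defaults 0.5 and 4).
#' @return 3D array in `[0, 1]`, same shape as `mask`.
#' @export
relax_substrate <- function(mask, which = c("phi", "psi"),
                            D_phi = 0.5, D_psi = 4) {
  which <- match.arg(which)
  check_field(mask, "mask")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  D <- if (which == "phi") D_phi else D_psi
  total <- if (which == "phi") 3 * 0.05 else 5 * 0.05
  # stable explicit substep: dt <= h^2 / (6 D), with margin
  nstep <- max(1L, ceiling(total / (1 / (8 * D))))
  out <- cpp_diffuse(mask + 0, D, total / nstep, nstep, 1)
  pmin(pmax(out, 0), 1)
}

# Trilinear resample of a spacing-1 lattice field onto a simulation grid.
interp_to_grid <- function(f, grid) {
  if (abs(grid$spacing - 1) < 1e-12 && all(dim(f) == grid$shape)) return(f)
  h <- grid$spacing
  x <- axis_coords(grid$shape[1], h)
  y <- axis_coords(grid$shape[2], h)
  z <- axis_coords(grid$shape[3], h)
  pts <- as.matrix(expand.grid(x = x, y = y, z = z))
  out <- cpp_trilinear(f, pts, 1)
  array(out, dim = grid$shape)
}

# Assemble the full substrate object from a binary mask built at spacing 1.
build_substrate <- function(mask, grid, kappa = 1, meta = list()) {
  phi <- relax_substrate(mask, "phi")
  psi <- relax_substrate(mask, "psi")
  psi <- pmax(psi, phi)  # sensing shell always covers the substrate itself
  phi <- interp_to_grid(phi, grid)
  psi <- pmax(interp_to_grid(psi, grid), phi)
  if (length(kappa) == 1) kappa <- array(kappa, dim = grid$shape)
  if (any(kappa <= 0)) stop("adhesion map must be positive everywhere")
  structure(list(mask = mask, phi = phi, psi = psi, kappa = kappa,
                 grid = grid, meta = meta),
            class = "pf_substrate")
}

#' @export
print.pf_substrate <- function(x, ...) {
  cat(sprintf("<pf_substrate %s, %d x %d x %d @ %g um, solid fraction %.3f>\n",
              if (is.null(x$meta$kind)) "?" else x$meta$kind,
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing, mean(x$mask)))
  invisible(x)
}

#' Flat substrate with a centred adhesive strip
#'
#' A flat slab whose adhesion map is `kappa_on` on a strip of the given
#' width (centred along x, running the full length of y) and `kappa_off`
#' elsewhere — the patterned-adhesion surface used to study cell
#' elongation along strips.
#'
#' @param grid simulation [grid_spec()].
#' @param strip_width strip width in um.
#' @param kappa_on,kappa_off adhesion on/off the strip (defaults 5 and 1).
#' @param base_height slab thickness in um (default 4).
#' @return A `pf_substrate`.
#' @export
make_flat_with_strip <- function(grid, strip_width, kappa_on = 5,
                                 kappa_off = 1, base_height = 4) {
  if (strip_width <= 0) stop("strip_width must be positive")
  ext <- grid$shape * grid$spacing
  n1 <- round(ext) # mask lattice at spacing 1
  mask <- array(0, dim = n1)
  z1 <- axis_coords(n1[3], 1)
  mask[, , z1 <= base_height] <- 1
  kappa <- array(kappa_off, dim = grid$shape)
  x <- axis_coords(grid$shape[1], grid$spacing)
  on <- abs(x - ext[1] / 2) <= strip_width / 2
  kappa[on, , ] <- kappa_on
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "strip", strip_width = strip_width,
                              kappa_on = kappa_on, kappa_off = kappa_off,
                              base_height = base_height))
}

#' Patterned surface of convex hemispherical protrusions
#'
#' A flat base carrying hemispherical bumps of the given radius on a square
#' lattice — the validation surface on which membrane tension makes a cell
#' move off a protrusion rather than rest atop it.
#'
#' @param grid simulation [grid_spec()].
#' @param radius bump radius in um (default 12, comparable to the cell).
#' @param pitch bump lattice spacing in um.
#' @param base_height base slab thickness in um (default 4).
#' @param kappa adhesion strength (default 1).
#' @return A `pf_substrate`; `meta$apex` holds the world coordinates of the
#'   central bump apex.
#' @export
make_hemisphere_array <- function(grid, radius = 12, pitch = 32,
                                  base_height = 4, kappa = 1) {
  ext <- grid$shape * grid$spacing
  n1 <- round(ext)
  x <- axis_coords(n1[1], 1); y <- axis_coords(n1[2], 1)
  z <- axis_coords(n1[3], 1)
  mask <- array(0, dim = n1)
  mask[, , z <= base_height] <- 1
  cx <- ext[1] / 2; cy <- ext[2] / 2
  offs <- expand.grid(mx = -2:2, my = -2:2)
  for (q in seq_len(nrow(offs))) {
    bx <- cx + offs$mx[q] * pitch; by <- cy + offs$my[q] * pitch
    if (bx < -radius || by < -radius || bx > ext[1] + radius ||
        by > ext[2] + radius) next
    d2 <- outer(outer((x - bx)^2, (y - by)^2, `+`), (z - base_height)^2, `+`)
    mask[d2 <= radius^2 & outer(array(TRUE, c(n1[1], n1[2])),
                                z >= base_height)] <- 1
  }
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "hemisphere", radius = radius,
                              pitch = pitch, base_height = base_height,
                              apex = c(cx, cy, base_height + radius)))
}

#' Layered random close packing of equal spheres
#'
#' Sequential "drop and settle" deposition: spheres are released at random
#' lateral positions above the bed (periodic in x and y) and relaxed
#' downhill by steepest descent with projection onto the pairwise
#' non-penetration constraint at contact distance `2 r (1 - sinter)`. Each
#' sphere takes the lowest of several candidate drops. The slight sinter
#' overlap at contact corresponds to interconnect windows of about a third
#' of the sphere diameter once the packing is templated; the bulk volume
#' fraction of the sphere union lands at the random-close-packing limit
#' (~0.64) and is reported in `meta`.
#'
#' @param radius sphere radius in um (default 35).
#' @param box numeric triple, packing region in um (each lateral side should
#'   be at least ~6 diameters for a meaningful bulk fraction).
#' @param seed integer seed; the generator is deterministic given it.
#' @param overlap_frac maximum allowed overlap: pairwise centre distance
#'   never falls below `2 r (1 - overlap_frac)` (default 0.35).
#' @param sinter deposition contact distance parameter: spheres rest at
#'   centre distance `2 r (1 - sinter)`. The default 0.0543 gives
#'   circle-of-intersection windows of 0.325 sphere diameters.
#' @param n_candidates candidate drops per sphere; the lowest resting
#'   position wins (default 4).
#' @param roll_budget sticky-particle rolling budget: how many successful
#'   descent moves a sphere may make after its first contact with the bed
#'   before it adheres. Controls the settled density; the default 4
#'   reproduces the random-close-packing union fraction ~0.64 together
#'   with the default sinter overlap.
#' @param min_fraction abort threshold on the achieved bulk fraction.
#' @return An object of class `pf_packing`: `centers` (n x 3 matrix),
#'   `radius`, `box`, `seed`, `fraction` (bulk union volume fraction),
#'   `meta`.
#' @export
pack_spheres_rcp <- function(radius = 35, box = c(420, 420, 420), seed = 1,
                             overlap_frac = 0.35, sinter = 0.0543,
                             n_candidates = 4, roll_budget = 4,
                             min_fraction = 0.60) {
  set.seed(seed)
  r <- radius
  dmin <- 2 * r * (1 - sinter)
  if (sinter > overlap_frac) stop("sinter cannot exceed overlap_frac")
  bx <- box[1]; by <- box[2]; bz <- box[3]
  fill_to <- bz + 2 * r
  centers <- matrix(numeric(0), ncol = 3)
  zmax <- 0
  repeat {
    best <- NULL
    for (cand in seq_len(n_candidates)) {
      pos <- c(runif(1, 0, bx), runif(1, 0, by), zmax + 2 * r)
      pos <- cpp_settle_sphere(pos, centers, dmin, r, bx, by, roll_budget)
      if (is.null(best) || pos[3] < best[3]) best <- pos
    }
    centers <- rbind(centers, best)
    zmax <- max(zmax, best[3])
    if (best[3] > fill_to) break
    if (nrow(centers) > 50 * bx * by * bz / ((4 / 3) * pi * r^3)) {
      stop("packing failed to fill the box")
    }
  }
  # bulk fraction measured away from the floor and the free surface
  zlo <- 2 * r; zhi <- bz - 2 * r
  sub <- centers
  sub[, 3] <- sub[, 3] - zlo
  frac <- cpp_sphere_union_fraction(sub, r, c(bx, by, zhi - zlo),
                                    h = max(r / 17.5, 0.5),
                                    periodic = c(TRUE, TRUE, FALSE))
  if (frac < min_fraction) {
    stop(sprintf("packing only reached bulk fraction %.3f (< %.2f)",
                 frac, min_fraction))
  }
  structure(list(centers = centers, radius = r, box = box, seed = seed,
                 fraction = frac,
                 meta = list(kind = "rcp", sinter = sinter,
                             overlap_frac = overlap_frac,
                             n_spheres = nrow(centers))),
            class = "pf_packing")
}

#' Estimate the sphere-union volume fraction of a packing
#'
#' Midpoint voxel integration (default) or Monte-Carlo point sampling of
#' the fraction of a region covered by the union of spheres, with periodic
#' wrapping in x and y.
#'
#' @param packing a `pf_packing`.
#' @param method `"voxel"` or `"mc"`.
#' @param n_points Monte-Carlo sample size (method `"mc"`).
#' @param seed Monte-Carlo seed.
#' @return Scalar volume fraction.
#' @export
packing_fraction <- function(packing, method = c("voxel", "mc"),
                             n_points = 2e5, seed = 1) {
  method <- match.arg(method)
  r <- packing$radius; box <- packing$box
  zlo <- 2 * r; zhi <- box[3] - 2 * r
  ctr <- packing$centers
  ctr[, 3] <- ctr[, 3] - zlo
  bb <- c(box[1], box[2], zhi - zlo)
  if (method == "voxel") {
    return(cpp_sphere_union_fraction(ctr, r, bb, h = max(r / 17.5, 0.5),
                                     periodic = c(TRUE, TRUE, FALSE)))
  }
  set.seed(seed)
  pts <- cbind(runif(n_points, 0, bb[1]), runif(n_points, 0, bb[2]),
               runif(n_points, 0, bb[3]))
  hit <- logical(n_points)
  chunk <- 5000L
  for (s in seq(1, n_points, by = chunk)) {
    ii <- s:min(s + chunk - 1, n_points)
    dx <- abs(outer(pts[ii, 1], ctr[, 1], `-`)); dx <- pmin(dx, bb[1] - dx)
    dy <- abs(outer(pts[ii, 2], ctr[, 2], `-`)); dy <- pmin(dy, bb[2] - dy)
    dz <- outer(pts[ii, 3], ctr[, 3], `-`)
    hit[ii] <- rowSums(dx^2 + dy^2 + dz^2 <= r^2) > 0
  }
  mean(hit)
}

# Voxelize the union of spheres on a spacing-1 lattice over a sub-box
# (a voxel is pore if its centre lies inside any sphere).
voxelize_spheres <- function(centers, radius, box) {
  n <- round(box)
  x <- axis_coords(n[1], 1); y <- axis_coords(n[2], 1); z <- axis_coords(n[3], 1)
  pore <- array(FALSE, dim = n)
  r2 <- radius^2
  for (q in seq_len(nrow(centers))) {
    cc <- centers[q, ]
    if (cc[1] < -radius || cc[1] > box[1] + radius ||
        cc[2] < -radius || cc[2] > box[2] + radius ||
        cc[3] < -radius || cc[3] > box[3] + radius) next
    d2 <- outer(outer((x - cc[1])^2, (y - cc[2])^2, `+`), (z - cc[3])^2, `+`)
    pore <- pore | (d2 <= r2)
  }
  pore
}

#' Particle-templated material from a sphere packing
#'
#' Voxelizes the union of packed spheres (the future pores) over a region
#' and inverts solid and void: the solid is the complement of the sphere
#' union, with circular interconnect windows wherever neighbouring spheres
#' overlap. For two spheres of radius r at centre distance `2 r (1 - ov)`
#' the window diameter is the circle-of-intersection diameter
#' `2 r sqrt(1 - (1 - ov)^2)`.
#'
#' @param packing a `pf_packing`.
#' @param grid simulation [grid_spec()]; its extent selects the sub-region
#'   of the packing to voxelize (from the origin).
#' @param kappa adhesion (default 1).
#' @return A `pf_substrate`.
#' @export
make_ptm <- function(packing, grid, kappa = 1) {
  ext <- grid$shape * grid$spacing
  pore <- voxelize_spheres(packing$centers, packing$radius, ext)
  mask <- array(as.numeric(!pore), dim = dim(pore))
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "ptm", radius = packing$radius,
                              seed = packing$seed,
                              pore_fraction = mean(pore)))
}

#' Simplified vertical three-pore interconnect structure
#'
#' Three collinear spherical pores along z with centre spacing chosen so the
#' circular windows between them have diameter
#' `interconnect_frac * sphere_diameter`; the structure is inverted so
#' everything outside the pores is solid. This isolates a single
#' pore-interconnect-pore motif of a particle-templated material.
#'
#' @param grid simulation [grid_spec()].
#' @param sphere_diameter pore diameter in um.
#' @param interconnect_frac window diameter as a fraction of the pore
#'   diameter, in (0, 0.5] (default 0.325).
#' @param kappa adhesion (default 1).
#' @return A `pf_substrate`; `meta` records the pore centres and the z
#'   coordinates of the two window planes.
#' @export
make_ptm_interconnect <- function(grid, sphere_diameter = 24,
                                  interconnect_frac = 0.325, kappa = 1) {
  if (interconnect_frac <= 0 || interconnect_frac > 0.5) {
    stop("interconnect_frac must lie in (0, 0.5]")
  }
  ext <- grid$shape * grid$spacing
  R <- sphere_diameter / 2
  gap <- sphere_diameter * sqrt(1 - interconnect_frac^2) # centre spacing
  cx <- ext[1] / 2; cy <- ext[2] / 2; cz <- ext[3] / 2
  centers <- cbind(cx, cy, cz + c(-gap, 0, gap))
  pore <- voxelize_spheres(centers, R, ext)
  mask <- array(as.numeric(!pore), dim = dim(pore))
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "ptm3", sphere_diameter = sphere_diameter,
                              interconnect_frac = interconnect_frac,
                              centers = centers,
                              window_z = cz + c(-gap / 2, gap / 2),
                              window_diameter = interconnect_frac *
                                sphere_diameter))
}

#' Hyperboloid channel with matched end and throat diameters
#'
#' A vertical channel whose pore is a one-sheet hyperboloid of revolution:
#' throat diameter `d_min` at mid-height, opening to `d_max` at both ends of
#' the channel section, continued by straight cylinders of diameter `d_max`
#' above and below. Compared to a pore-interconnect motif with the same
#' maximum and minimum diameters, the wall curvature at the throat is much
#' lower — the control geometry separating aperture from curvature.
#'
#' @param grid simulation [grid_spec()].
#' @param d_max,d_min end and throat diameters in um (`d_min < d_max`).
#' @param length channel section length in um.
#' @param kappa adhesion (default 1).
#' @return A `pf_substrate`; `meta$throat_z` is the bottleneck plane.
#' @export
make_hyperboloid <- function(grid, d_max = 24, d_min = 7.8, length = 24,
                             kappa = 1) {
  if (d_min >= d_max) stop("d_min must be smaller than d_max")
  ext <- grid$shape * grid$spacing
  n1 <- round(ext)
  x <- axis_coords(n1[1], 1); y <- axis_coords(n1[2], 1); z <- axis_coords(n1[3], 1)
  cx <- ext[1] / 2; cy <- ext[2] / 2; z0 <- ext[3] / 2
  a <- (length / 2) / sqrt((d_max / d_min)^2 - 1)
  rad <- function(zz) {
    w <- abs(zz - z0)
    r <- (d_min / 2) * sqrt(1 + (pmin(w, length / 2) / a)^2)
    r[w > length / 2] <- d_max / 2
    r
  }
  r2xy <- outer((x - cx)^2, (y - cy)^2, `+`)
  pore <- array(FALSE, dim = n1)
  for (k in seq_along(z)) pore[, , k] <- r2xy <= rad(z[k])^2
  mask <- array(as.numeric(!pore), dim = n1)
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "hyperboloid", d_max = d_max,
                              d_min = d_min, length = length,
                              throat_z = z0))
}
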