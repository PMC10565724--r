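#' Cell centroid
#'
#' Centroid of the uniform-density solid bounded by the rho = 0.5 surface
#' (rho-weighted over that region).
#'
#' @param rho cell field.
#' @param grid grid or spacing.
#' @return Numeric 3-vector, world coordinates in um.
#' @export
cell_centroid <- function(rho, grid) {
  h <- as_spacing(grid)
  d <- dim(rho)
  w <- rho * (rho >= 0.5)
  tot <- sum(w)
  if (tot == 0) stop("empty cell: no voxel with rho >= 0.5")
  wx <- apply(w, 1, sum); wy <- apply(w, 2, sum); wz <- apply(w, 3, sum)
  c(sum(axis_coords(d[1], h) * wx),
    sum(axis_coords(d[2], h) * wy),
    sum(axis_coords(d[3], h) * wz)) / tot
}

#' Displacement series of a trajectory
#'
#' Distance of the centroid from its initial position at each recorded
#' time, `r(t) = |centroid(t) - centroid(0)|`, so `r(0) = 0`.
#'
#' @param traj a `pf_trajectory` from [simulate_cell()], or a data frame
#'   with columns `t`, `cx`, `cy`, `cz`.
#' @return A data frame with columns `t` and `r`.
#' @export
centroid_displacement <- function(traj) {
  m <- if (inherits(traj, "pf_trajectory")) traj$metrics else traj
  if (nrow(m) < 1) stop("trajectory has no snapshots")
  data.frame(t = m$t,
             r = sqrt((m$cx - m$cx[1])^2 + (m$cy - m$cy[1])^2 +
                      (m$cz - m$cz[1])^2))
}

#' Centered-difference velocity
#'
#' `v_i = (r_[i+1] - r_[i-1]) / (t_[i+1] - t_[i-1])` in the interior with
#' one-sided differences at the endpoints. Exact for a quadratic `r(t)`
#' sampled uniformly.
#'
#' @param r_series data frame with columns `t` and `r` (see
#'   [centroid_displacement()]).
#' @return The input with a `v` column added (um per time unit).
#' @export
velocity_series <- function(r_series) {
  t <- r_series$t; r <- r_series$r; n <- length(t)
  if (n < 3) stop("need at least 3 samples for a centered difference")
  v <- numeric(n)
  v[1] <- (r[2] - r[1]) / (t[2] - t[1])
  v[n] <- (r[n] - r[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  v[i] <- (r[i + 1] - r[i - 1]) / (t[i + 1] - t[i - 1])
  r_series$v <- v
  r_series
}

#' Principal inertia eigenvalues of the cell shape
#'
#' Eigenvalues of the second-moment (inertia) tensor
#' `I = sum m (|r|^2 Id - r r^T)` of the uniform solid bounded by rho = 0.5,
#' about its centroid, sorted `k11 >= k22 >= k33`. A ball gives three equal
#' values; a thin disk gives `k11 / k22 -> 2` with `k22 ~ k33`
#' (the axis moment of a disk is twice the diametral moment), which is the
#' signature used to classify flattened cells.
#'
#' @inheritParams cell_centroid
#' @return Named numeric vector `c(k11, k22, k33)`.
#' @export
inertia_eigenvalues <- function(rho, grid) {
  h <- as_spacing(grid)
  d <- dim(rho)
  sel <- which(rho >= 0.5, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("empty cell: no voxel with rho >= 0.5")
  xyz <- (sel - 0.5) * h
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  m <- h^3
  xx <- sum(xc[, 1]^2) * m; yy <- sum(xc[, 2]^2) * m; zz <- sum(xc[, 3]^2) * m
  xy <- sum(xc[, 1] * xc[, 2]) * m
  xz <- sum(xc[, 1] * xc[, 3]) * m
  yz <- sum(xc[, 2] * xc[, 3]) * m
  I <- matrix(c(yy + zz, -xy, -xz,
                -xy, xx + zz, -yz,
                -xz, -yz, xx + yy), 3, 3)
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  stats::setNames(ev, c("k11", "k22", "k33"))
}

#' Shape energy of the cell
#'
#' `E_shape = integral of (D_rho/2)|grad rho|^2 + (1/4) rho^2 (1 - rho)^2
#'            + adh_scale kappa(x) grad Phi . grad g(rho)  dV`,
#' with `g(rho) = rho^2 (3 - 2 rho)` the cubic interpolant:
#' the diffuse membrane energy (gradient plus Allen-Cahn double well, with
#' the well prefactor matching the cubic boundary term at delta = 1/2), plus
#' the integrated adhesion reward — the same contact energy whose
#' variational derivative drives adhesion in the dynamics. It is negative
#' where the cell is in conformal contact with a substrate (the interface
#' gradients are then anti-parallel). Grows with membrane area at fixed
#' volume; only relative changes along a trajectory are meaningful.
#'
#' @inheritParams cell_centroid
#' @param substrate substrate or `NULL`.
#' @param params a [model_params()].
#' @return Scalar energy (nondimensional units).
#' @export
shape_energy <- function(rho, substrate, params, grid) {
  h <- as_spacing(grid)
  g <- cpp_gradient(rho, h)
  g2 <- g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2
  e <- params$D_rho / 2 * g2 + 0.25 * rho^2 * (1 - rho)^2
  if (!is.null(substrate)) {
    gp <- cpp_gradient(substrate$phi, h)
    kap <- substrate$kappa
    if (length(kap) == 1) kap <- array(kap, dim = dim(rho))
    gprime <- 6 * rho * (1 - rho)   # d g / d rho, g = rho^2 (3 - 2 rho)
    e <- e + params$adh_scale * kap * gprime *
      (gp[, , , 1] * g[, , , 1] + gp[, , , 2] * g[, , , 2] +
       gp[, , , 3] * g[, , , 3])
  }
  sum(e) * h^3
}

#' Mean z-component of the polarity field
#'
#' rho-weighted average of `p_z` over the cell region (rho >= 0.5). The sign
#' tracks the net direction of actin-driven motion along z; a persistent
#' sign reversal marks a redirection event.
#'
#' @param p polarity field (4D array).
#' @param rho cell field.
#' @return Scalar, dimensionless.
#' @export
mean_pz <- function(p, rho) {
  w <- rho * (rho >= 0.5)
  tot <- sum(w)
  if (tot == 0) stop("empty cell: no voxel with rho >= 0.5")
  sum(p[, , , 3] * w) / tot
}

#' Projected aspect ratio
#'
#' Projects the rho >= 0.5 solid along an axis onto a 2D mask and returns
#' the square root of the ratio of the two second-moment eigenvalues of that
#' mask (major over minor axis length). A ball projects to 1; a 2:1:1
#' ellipsoid seen along a short axis gives 2.
#'
#' @inheritParams cell_centroid
#' @param normal_axis projection axis, 1 (x), 2 (y) or 3 (z); default 3
#'   (projection onto a flat substrate).
#' @return Scalar aspect ratio >= 1.
#' @export
aspect_ratio_projection <- function(rho, grid, normal_axis = 3) {
  h <- as_spacing(grid)
  mask2d <- apply(rho >= 0.5, setdiff(1:3, normal_axis), any)
  sel <- which(mask2d, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("empty cell: no voxel with rho >= 0.5")
  uv <- (sel - 0.5) * h
  uc <- sweep(uv, 2, colMeans(uv))
  M <- crossprod(uc) / nrow(uc)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), .Machine$double.eps))
}

#' Cell-substrate contact area
#'
#' Diffuse proxy for the membrane area adjacent to the substrate:
#' `integral chi(rho) min(Psi/psi_ref, 1)^2 dV` normalized by the mean
#' membrane thickness `integral chi dV / A`, so the result is in um^2 and
#' matches the projected footprint for a cell spread on a flat slab (the
#' saturating weight compensates for the sensing shell being thinner than
#' the membrane band). Zero (to rounding) when the cell is far from any
#' substrate; using the sensing field Psi makes "contact" include the
#' sensing shell, threshold-free.
#'
#' @inheritParams cell_centroid
#' @param substrate substrate object.
#' @param G membrane indicator steepness (default 14).
#' @param psi_ref sensing level treated as full contact (default 0.1,
#'   calibrated so a flat spread cell reads its projected footprint).
#' @return Scalar contact area in um^2.
#' @export
contact_area <- function(rho, substrate, grid, G = 14, psi_ref = 0.1) {
  h <- as_spacing(grid)
  # membrane weight: chi with its bulk floor removed (for wide indicators
  # chi(0) is not negligible and would otherwise count background voxels)
  chi <- pmax(membrane_indicator(rho, G) - membrane_indicator(0, G), 0)
  A <- surface_area(rho, grid)
  if (A <= 0 || sum(chi) == 0) return(0)
  thick <- sum(chi) * h^3 / A
  # sensing weight saturates at the contact standoff (Psi ~ psi_ref there)
  w <- pmin(substrate$psi / psi_ref, 1)^2
  sum(chi * w) * h^3 / thick
}

#' Membrane glyph samples of the polarity field
#'
#' Block-averages the polarity field over `stride`-voxel blocks restricted
#' to the membrane region (`chi > 0.1`) and flags the `top_n` glyphs of
#' highest magnitude (the convention used to display dominant polymerization
#' directions).
#'
#' @inheritParams cell_centroid
#' @param p polarity field (4D array).
#' @param stride block edge in voxels (default 3).
#' @param top_n how many highest-magnitude glyphs to flag (default 100).
#' @param G membrane indicator steepness.
#' @return Data frame with glyph centre coordinates (um), mean polarity
#'   components, magnitude `mag`, and logical `top`.
#' @export
p_field_glyphs <- function(p, rho, grid, stride = 3, top_n = 100, G = 14) {
  h <- as_spacing(grid)
  d <- dim(rho)
  chi <- membrane_indicator(rho, G)
  memb <- chi > 0.1
  if (!any(memb)) stop("no membrane region (chi > 0.1)")
  sel <- which(memb, arr.ind = TRUE)
  block <- floor((sel - 1) / stride)
  key <- block[, 1] + 1e4 * (block[, 2] + 1e4 * block[, 3])
  sp <- split(seq_len(nrow(sel)), key)
  px <- p[, , , 1][memb]; py <- p[, , , 2][memb]; pz <- p[, , , 3][memb]
  xs <- (sel[, 1] - 0.5) * h; ys <- (sel[, 2] - 0.5) * h
  zs <- (sel[, 3] - 0.5) * h
  out <- do.call(rbind, lapply(sp, function(ii) {
    c(mean(xs[ii]), mean(ys[ii]), mean(zs[ii]),
      mean(px[ii]), mean(py[ii]), mean(pz[ii]))
  }))
  out <- as.data.frame(out)
  names(out) <- c("x", "y", "z", "px", "py", "pz")
  rownames(out) <- NULL
  out$mag <- sqrt(out$px^2 + out$py^2 + out$pz^2)
  ord <- order(out$mag, decreasing = TRUE)
  out$top <- FALSE
  out$top[ord[seq_len(min(top_n, nrow(out)))]] <- TRUE
  out
}

#' Gaussian curvature of an implicit surface
#'
#' Gaussian curvature of the level sets of a smooth field, computed from its
#' gradient and Hessian as `K = (grad f' adj(H) grad f) / |grad f|^4`. Used
#' to verify the saddle-dominated (non-positive K) character of spinodal
#' substrate surfaces; a sphere of radius R gives `K = 1/R^2`.
#'
#' @inheritParams fd_gradient
#' @param grad_min bulk cutoff; K is NA where `|grad f|` is below it.
#' @return 3D array of Gaussian curvature (1/um^2), NA in the bulk.
#' @export
implicit_gaussian_curvature <- function(f, grid, grad_min = 1e-3) {
  h <- as_spacing(grid)
  g <- cpp_gradient(f, h)
  gx <- g[, , , 1]; gy <- g[, , , 2]; gz <- g[, , , 3]
  gxx <- cpp_gradient(gx, h); gyy <- cpp_gradient(gy, h)
  gzz <- cpp_gradient(gz, h)
  fxx <- gxx[, , , 1]; fxy <- gxx[, , , 2]; fxz <- gxx[, , , 3]
  fyy <- gyy[, , , 2]; fyz <- gyy[, , , 3]
  fzz <- gzz[, , , 3]
  # adjugate of the Hessian
  a11 <- fyy * fzz - fyz^2
  a22 <- fxx * fzz - fxz^2
  a33 <- fxx * fyy - fxy^2
  a12 <- fyz * fxz - fxy * fzz
  a13 <- fxy * fyz - fyy * fxz
  a23 <- fxy * fxz - fxx * fyz
  num <- gx * (a11 * gx + a12 * gy + a13 * gz) +
         gy * (a12 * gx + a22 * gy + a23 * gz) +
         gz * (a13 * gx + a23 * gy + a33 * gz)
  gn2 <- gx^2 + gy^2 + gz^2
  K <- num / gn2^2
  K[sqrt(gn2) < grad_min] <- NA_real_
  K
}
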