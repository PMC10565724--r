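#' Initialize a cell on a grid
#'
#' The cell starts as a binary occupancy field (a 17 um cube by default, or a
#' sphere of equal resolution) with a unit-magnitude polarity vector at every
#' occupied voxel. The initial volume `V0` is recorded; the reference minimum
#' area `A0` comes from a relaxed free cell (see [free_cell_reference()]) and
#' may be attached here or supplied later to [simulate_cell()].
#'
#' @param grid a [grid_spec()].
#' @param center world coordinates (um) of the cell centre.
#' @param edge cube edge length in um (default 17); for `shape = "sphere"`
#'   the radius is `radius`.
#' @param shape `"cube"` or `"sphere"`.
#' @param radius sphere radius in um (only for `shape = "sphere"`).
#' @param p_dir initial polarity direction (unit magnitude is imposed), or
#'   `NULL` for a quiescent cell with p = 0. Default points straight down.
#' @param substrate optional [substrate][make_flat_with_strip] the placement
#'   is checked against: any occupied voxel with Phi > 0.01 is an error.
#' @param A0 optional reference minimum surface area.
#' @return An object of class `pf_cell`: fields `rho` (3D), `p` (4D),
#'   `V0`, `A0`, `t`, `grid`.
#' @export
initialize_cell <- function(grid, center, edge = 17, shape = c("cube", "sphere"),
                            radius = edge / 2, p_dir = c(0, 0, -1),
                            substrate = NULL, A0 = NA_real_) {
  shape <- match.arg(shape)
  h <- grid$spacing
  x <- axis_coords(grid$shape[1], h)
  y <- axis_coords(grid$shape[2], h)
  z <- axis_coords(grid$shape[3], h)
  rho <- field_array(grid)
  if (shape == "cube") {
    # half-open interval per axis: the voxel count is translation invariant
    ix <- x >= center[1] - edge / 2 & x < center[1] + edge / 2
    iy <- y >= center[2] - edge / 2 & y < center[2] + edge / 2
    iz <- z >= center[3] - edge / 2 & z < center[3] + edge / 2
    rho[ix, iy, iz] <- 1
  } else {
    dx2 <- outer(outer((x - center[1])^2, (y - center[2])^2, `+`),
                 (z - center[3])^2, `+`)
    rho[dx2 <= radius^2] <- 1
  }
  if (!any(rho > 0)) stop("initial cell is empty on this grid")
  if (!is.null(substrate)) {
    if (any(substrate$phi[rho > 0] > 0.01)) {
      stop("cell placement overlaps the substrate (Phi > 0.01)")
    }
  }
  p <- array(0, dim = c(grid$shape, 3))
  if (!is.null(p_dir)) {
    p_dir <- p_dir / sqrt(sum(p_dir^2))
    inside <- rho > 0
    for (a in 1:3) {
      comp <- array(0, dim = grid$shape)
      comp[inside] <- p_dir[a]
      p[, , , a] <- comp
    }
  }
  structure(list(rho = rho, p = p, V0 = cell_volume(rho, grid),
                 A0 = A0, t = 0, grid = grid),
            class = "pf_cell")
}

#' @export
print.pf_cell <- function(x, ...) {
  cat(sprintf("<pf_cell t = %g, V0 = %g um^3, A0 = %s um^2, %d x %d x %d @ %g um>\n",
              x$t, x$V0, format(x$A0), x$grid$shape[1], x$grid$shape[2],
              x$grid$shape[3], x$grid$spacing))
  invisible(x)
}

#' Interface setpoint field delta
#'
#' `delta = 1/2 + mu (V0 - V) - sigma |p|^2`: the local target of the cubic
#' boundary term. Volume excess (V > V0) lowers delta so the interface
#' retracts; local contractility (|p|^2) lowers it further.
#'
#' @param rho,p cell fields.
#' @param params a [model_params()].
#' @param V0 reference volume (um^3).
#' @param grid grid or spacing.
#' @return 3D array of delta values.
#' @export
delta_field <- function(rho, p, params, V0, grid) {
  V <- cell_volume(rho, grid)
  p2 <- p[, , , 1]^2 + p[, , , 2]^2 + p[, , , 3]^2
  0.5 + params$mu * (V0 - V) - params$sigma * p2
}

#' Rotate a polymerization direction tangential to the substrate
#'
#' Given the local cell gradient and substrate gradient, returns a vector
#' with the magnitude of `grad_rho` directed along the component of
#' `grad_rho` perpendicular to `grad_phi` (i.e. tangential to the substrate
#' surface). Far from any substrate (`|grad_phi| < 1e-6`) the vector is
#' returned unchanged; a vector exactly normal to the surface maps to zero.
#'
#' @param grad_rho,grad_phi numeric 3-vectors.
#' @return A numeric 3-vector.
#' @export
p_hat_rotate <- function(grad_rho, grad_phi) {
  np <- sqrt(sum(grad_phi^2))
  if (np < 1e-6) return(grad_rho)
  nhat <- grad_phi / np
  tang <- grad_rho - sum(grad_rho * nhat) * nhat
  tn <- sqrt(sum(tang^2))
  if (tn < 1e-12) return(c(0, 0, 0))
  tang * (sqrt(sum(grad_rho^2)) / tn)
}

# Expand a substrate into the arrays the kernels need. NULL means free space.
# `wet` is the adhesion (wetting) potential div(kappa grad Phi): the
# variational force of the contact energy kappa grad Phi . grad g(rho).
substrate_precompute <- function(substrate, grid) {
  if (is.null(substrate)) {
    z <- field_array(grid)
    return(list(phi2 = z, psi = z, kgx = z, kgy = z, kgz = z, wet = z))
  }
  gphi <- fd_gradient(substrate$phi, grid)
  kap <- substrate$kappa
  if (length(kap) == 1) kap <- array(kap, dim = grid$shape)
  kgx <- kap * gphi[, , , 1]
  kgy <- kap * gphi[, , , 2]
  kgz <- kap * gphi[, , , 3]
  wet <- fd_gradient(kgx, grid)[, , , 1] + fd_gradient(kgy, grid)[, , , 2] +
    fd_gradient(kgz, grid)[, , , 3]
  list(phi2 = substrate$phi^2, psi = substrate$psi,
       kgx = kgx, kgy = kgy, kgz = kgz, wet = wet)
}

#' Actin source term (reference implementation)
#'
#' `S = Psi [ (1 - theta) Phat(grad rho) + theta grad rho ]
#'      + epsilon chi exp(chi zeta c) grad rho`.
#' The first part splits polymerization at a substrate between pushing into
#' it and turning parallel to it; the second is the membrane-tension factor,
#' added independently of Psi so that tension acts on the whole membrane,
#' not only where the cell touches a surface. The full source enters the
#' polarity equation as `- beta S` (the cell gradient points inward, so the
#' generated polarity points along the outward normal).
#'
#' This is the plain-R reference used for testing; the integrator fuses the
#' same expression in compiled code.
#'
#' @param rho cell field.
#' @param substrate substrate object or `NULL`.
#' @param zeta global membrane stretch `f0 T (A - A0)/A0`.
#' @param params a [model_params()].
#' @param grid grid or spacing.
#' @return 4D array (vector field).
#' @export
actin_source <- function(rho, substrate, zeta, params, grid) {
  g <- fd_gradient(rho, grid)
  chi <- membrane_indicator(rho, params$G)
  cc <- interface_curvature(rho, grid)
  pre <- substrate_precompute(substrate, if (inherits(grid, "pf_grid")) grid
                              else grid_spec(dim(rho), as_spacing(grid)))
  d <- dim(rho)
  S <- array(0, dim = c(d, 3))
  kn <- sqrt(pre$kgx^2 + pre$kgy^2 + pre$kgz^2)
  gmag <- sqrt(g[, , , 1]^2 + g[, , , 2]^2 + g[, , , 3]^2)
  # tangential rotation where a substrate is sensed
  nx <- ifelse(kn >= 1e-6, pre$kgx / pmax(kn, 1e-300), 0)
  ny <- ifelse(kn >= 1e-6, pre$kgy / pmax(kn, 1e-300), 0)
  nz <- ifelse(kn >= 1e-6, pre$kgz / pmax(kn, 1e-300), 0)
  dn <- g[, , , 1] * nx + g[, , , 2] * ny + g[, , , 3] * nz
  tx <- g[, , , 1] - dn * nx
  ty <- g[, , , 2] - dn * ny
  tz <- g[, , , 3] - dn * nz
  tn <- sqrt(tx^2 + ty^2 + tz^2)
  scl <- ifelse(tn < 1e-12, 0, gmag / pmax(tn, 1e-300))
  px <- ifelse(kn >= 1e-6, tx * scl, g[, , , 1])
  py <- ifelse(kn >= 1e-6, ty * scl, g[, , , 2])
  pz <- ifelse(kn >= 1e-6, tz * scl, g[, , , 3])
  wten <- params$epsilon * chi * exp(pmin(pmax(chi * zeta * cc, -8), 8))
  S[, , , 1] <- pre$psi * ((1 - params$theta) * px + params$theta * g[, , , 1]) +
    wten * g[, , , 1]
  S[, , , 2] <- pre$psi * ((1 - params$theta) * py + params$theta * g[, , , 2]) +
    wten * g[, , , 2]
  S[, , , 3] <- pre$psi * ((1 - params$theta) * pz + params$theta * g[, , , 3]) +
    wten * g[, , , 3]
  S
}

#' Right-hand side of the cell equation (reference implementation)
#'
#' `drho/dt = D_rho lap rho - alpha p . grad rho
#'            - kappa(x) grad Phi . grad rho
#'            + adh_scale div(kappa(x) grad Phi) 6 rho (1 - rho)
#'            - lambda rho Phi^2 + (1 - rho)(rho - (1 - delta)) rho`.
#' The adhesion term is the Allen-Cahn variational force of the contact
#' energy `kappa grad Phi . grad g(rho)` (g the cubic interpolant): it pulls
#' the interface into conformal contact with strength proportional to the
#' local adhesivity kappa, acts only at the interface, and rewards contact
#' in the shape energy. The exclusion term expels the cell from the solid;
#' the bistable boundary term keeps the bulk phases rho = 0 and rho = 1
#' stable with an interface threshold at `1 - delta`, so with
#' `delta > 1/2` the boundary advances and with `delta < 1/2` it retracts.
#'
#' @param state a `pf_cell`.
#' @param substrate substrate or `NULL`.
#' @param params a [model_params()].
#' @return 3D array, the time derivative of rho.
#' @export
rho_rhs <- function(state, substrate, params) {
  grid <- state$grid
  pre <- substrate_precompute(substrate, grid)
  delta <- delta_field(state$rho, state$p, params, state$V0, grid)
  g <- fd_gradient(state$rho, grid)
  adv <- params$alpha * (state$p[, , , 1] * g[, , , 1] +
                         state$p[, , , 2] * g[, , , 2] +
                         state$p[, , , 3] * g[, , , 3])
  # upwind one-sided differences for the conformal adhesion transport
  upw <- function(f, axis, vel) {
    h <- grid$spacing
    d <- dim(f)
    sh <- function(off) {
      idx <- pmin(pmax(seq_len(d[axis]) + off, 1), d[axis])
      if (axis == 1) f[idx, , , drop = FALSE]
      else if (axis == 2) f[, idx, , drop = FALSE]
      else f[, , idx, drop = FALSE]
    }
    back <- (f - sh(-1)) / h
    fwd <- (sh(1) - f) / h
    ifelse(vel > 0, back, ifelse(vel < 0, fwd, 0))
  }
  adh <- -(pre$kgx * upw(state$rho, 1, pre$kgx) +
           pre$kgy * upw(state$rho, 2, pre$kgy) +
           pre$kgz * upw(state$rho, 3, pre$kgz)) +
    params$adh_scale * pre$wet * 6 * state$rho * (1 - state$rho)
  out <- params$D_rho * fd_laplacian(state$rho, grid) - adv + adh -
    params$lambda * state$rho * pre$phi2 +
    (1 - state$rho) * (state$rho - (1 - delta)) * state$rho
  if (any(!is.finite(out))) stop("non-finite value in rho right-hand side")
  out
}

#' Right-hand side of the polarity equation (reference implementation)
#'
#' `dp/dt = D_p lap p - tau1_inv p - gamma (grad rho . p) p - Phi^2 p
#'          - beta S`, with the source `S` from [actin_source()]. With no
#' source the polarity decays at least as fast as `exp(-tau1_inv t)`; inside
#' the substrate the `Phi^2` term removes it quickly.
#'
#' @inheritParams rho_rhs
#' @param zeta membrane stretch; if `NULL` it is computed from the state's
#'   `A0` (zero when `A0` is not set).
#' @return 4D array, the time derivative of p.
#' @export
p_rhs <- function(state, substrate, params, zeta = NULL) {
  grid <- state$grid
  if (is.null(zeta)) {
    zeta <- if (is.na(state$A0)) 0 else
      max(0, params$f0T * (surface_area(state$rho, grid) - state$A0) /
               state$A0)
  }
  g <- fd_gradient(state$rho, grid)
  pre <- substrate_precompute(substrate, grid)
  S <- actin_source(state$rho, substrate, zeta, params, grid)
  gp <- g[, , , 1] * state$p[, , , 1] + g[, , , 2] * state$p[, , , 2] +
    g[, , , 3] * state$p[, , , 3]
  out <- array(0, dim = dim(state$p))
  for (a in 1:3) {
    out[, , , a] <- params$D_p * fd_laplacian(state$p[, , , a], grid) -
      params$tau1_inv * state$p[, , , a] -
      params$gamma * gp * state$p[, , , a] -
      pre$phi2 * state$p[, , , a] - params$beta * S[, , , a]
  }
  if (any(!is.finite(out))) stop("non-finite value in p right-hand side")
  out
}

# Advance the state by `duration` time units with the fused compiled kernel.
# Returns the updated state plus the last block diagnostics.
advance_cell <- function(state, pre, params, duration,
                         refresh_every = 10, full_domain = FALSE,
                         band_tol = 1e-8) {
  nsub <- max(1L, as.integer(round(duration / params$dt)))
  A0 <- if (is.na(state$A0)) surface_area(state$rho, state$grid) else state$A0
  res <- cpp_simulate_block(state$rho, state$p[, , , 1], state$p[, , , 2],
                            state$p[, , , 3], pre$phi2, pre$psi,
                            pre$kgx, pre$kgy, pre$kgz, pre$wet,
                            state$grid$spacing, params$dt, nsub,
                            as.integer(refresh_every), unclass(params),
                            state$V0, A0, 1e-8, 1e-6, full_domain, band_tol)
  if (!res$ok) stop("integration aborted: ", res$error)
  state$rho <- res$rho
  p <- array(0, dim = c(state$grid$shape, 3))
  p[, , , 1] <- res$px; p[, , , 2] <- res$py; p[, , , 3] <- res$pz
  state$p <- p
  state$t <- state$t + nsub * params$dt
  attr(state, "diag") <- list(A = res$A, V = res$V, zeta = res$zeta,
                              max_drho = res$max_drho,
                              n_active = res$n_active)
  state
}

#' Advance a cell state by one (or a few) explicit Euler steps
#'
#' One update of rho and p restricted to the active region: all voxels with
#' rho >= 0.01 plus a 1 um buffer. Fields outside the band are untouched.
#' The surface area, membrane stretch and curvature entering the
#' membrane-tension factor are recomputed every step.
#'
#' @param state a `pf_cell`.
#' @param substrate substrate or `NULL`.
#' @param params a [model_params()].
#' @param duration time units to advance (default one `dt`).
#' @param full_domain integrate over the whole grid instead of the active
#'   band (for verification; slower, same result to rounding).
#' @return The advanced `pf_cell` (with an integration diagnostic attribute).
#' @export
step_cell <- function(state, substrate, params, duration = params$dt,
                      full_domain = FALSE) {
  pre <- substrate_precompute(substrate, state$grid)
  advance_cell(state, pre, params, duration, full_domain = full_domain)
}

#' Relax a free cell to its stationary reference state
#'
#' Integrates a cell with no substrate and initially quiescent polarity
#' until the residual `max |drho/dt|` falls below `tol`, and returns the
#' resulting minimum surface area `A0` together with the steady state. The
#' membrane stretch is held at zero during the relaxation, which is
#' self-consistent at convergence (A = A0 implies zeta = 0). Results are
#' cached per parameter set, cell size and spacing.
#'
#' @param params a [model_params()].
#' @param edge,shape,radius initial cell geometry as in [initialize_cell()].
#' @param tol residual tolerance on `max |drho/dt|` (default 1e-6).
#' @param t_max giving-up time (default 500; error if not converged).
#' @return A list with `A0`, `V` (steady volume) and `state` (a `pf_cell`
#'   whose `A0` field is set).
#' @export
free_cell_reference <- function(params, edge = 17, shape = "cube",
                                radius = edge / 2, tol = 1e-6, t_max = 500) {
  if (params$epsilon == 0) {
    # without the tension term nothing reads A0; define the reference from
    # the common parameter set so tension-on/off pairs share one geometry
    params$epsilon <- formals(model_params)$epsilon
  }
  key <- sprintf("freecell|%s|%g|%g|%g|%g|%g|%g|%g|%g|%g",
                 shape, edge, radius, params$dx, params$dt, params$D_rho,
                 params$mu, params$sigma, params$epsilon, params$G)
  if (!is.null(.pf_cache[[key]])) return(.pf_cache[[key]])
  h <- params$dx
  ext <- if (shape == "cube") edge else 2 * radius
  # generous clearance: diffuse tails must not couple to the mirror walls
  n <- ceiling((ext + 24) / h / 2) * 2
  g <- grid_spec(rep(n, 3), h)
  ctr <- rep(n * h / 2, 3)
  st <- initialize_cell(g, ctr, edge = edge, shape = shape, radius = radius,
                        p_dir = NULL)
  pars0 <- params
  # stationary reference: no actin generation, no membrane stretch; the
  # relaxed droplet is the minimum-area state the stretch is measured from
  pars0$beta <- 0
  pars0$f0T <- 0
  pre <- substrate_precompute(NULL, g)
  st$A0 <- surface_area(st$rho, g)  # placeholder, unused while f0T = 0
  repeat {
    st <- advance_cell(st, pre, pars0, 5)
    dg <- attr(st, "diag")
    if (dg$max_drho / params$dt < tol) break
    if (st$t >= t_max) {
      stop(sprintf("free cell failed to reach steady state by t = %g (residual %g)",
                   t_max, dg$max_drho / params$dt))
    }
  }
  A0 <- surface_area(st$rho, g)
  st$A0 <- A0
  V <- cell_volume(st$rho, g)
  if (V < 0.5 * st$V0) {
    stop(sprintf(paste("free cell dissolved during relaxation (V = %.0f of",
                       "V0 = %.0f): the cell is below the stable droplet",
                       "size for these parameters"), V, st$V0))
  }
  out <- list(A0 = A0, V = V, state = st)
  .pf_cache[[key]] <- out
  out
}
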