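#' Model parameters
#'
#' Constructs the full nondimensional parameter set of the migration model,
#' defaulting to the common values used throughout (deviations are passed
#' explicitly). Time and length scales are set by the actin depolymerization
#' rate and the actin diffusivity: 1 time unit = 10 s, 1 length unit = 1 um.
#'
#' @param D_rho diffusion of the cell boundary (default 1).
#' @param D_phi diffusion used to relax the substrate boundary Phi (0.5).
#' @param D_psi diffusion used to relax the sensing boundary Psi (4).
#' @param D_p diffusion of the actin polarity field (0.2).
#' @param alpha advection of the cell with actin (2).
#' @param kappa adhesion strength; 1 by default, raised to 5 on adhesive
#'   strips. May be overridden per-substrate via its spatial adhesion map.
#' @param lambda exclusion of the cell from the substrate (5).
#' @param tau1_inv actin depolymerization rate (0.1).
#' @param T_memb membrane extensibility (1).
#' @param beta actin generation prefactor (3).
#' @param epsilon weight of the membrane tension term (0.34).
#' @param sigma acto-myosin contraction (0.2).
#' @param gamma symmetry breaking of myosin motors at the cell rear (0.05).
#' @param theta ratio of substrate "pushing" to "turning" polymerization,
#'   in (0, 1) (default 0.4).
#' @param mu strength of volume conservation (0.001).
#' @param G membrane width steepness (14).
#' @param f0 actin monomer size over thermal energy; only the product
#'   `f0 * T_memb` enters the membrane stretch zeta (default 1).
#' @param adh_scale normalization of the adhesion wetting force relative to
#'   the tabulated kappa scale (default 0.1): the adhesion term is
#'   `adh_scale * div(kappa grad Phi) * 6 rho (1 - rho)`. Calibrated once so
#'   that kappa = 1 gives a weakly wetting, rounded cell and kappa = 5 a
#'   strongly spread cell, the two regimes the adhesive-strip experiments
#'   distinguish.
#' @param dx lattice spacing in um (default 0.5).
#' @param dt time step (default 0.01). The constructor rejects
#'   `dt > 0.2 dx^2 / max(D_rho, D_p, 1)` to pre-empt explicit-Euler blowup.
#' @param t_end default total simulation time, nondimensional (500, i.e.
#'   5000 s).
#' @return An object of class `pf_params` (a named list).
#' @examples
#' p <- model_params()
#' p$epsilon           # 0.34, the membrane tension weight
#' @export
model_params <- function(D_rho = 1, D_phi = 0.5, D_psi = 4, D_p = 0.2,
                         alpha = 2, kappa = 1, lambda = 5, tau1_inv = 0.1,
                         T_memb = 1, beta = 3, epsilon = 0.34, sigma = 0.2,
                         gamma = 0.05, theta = 0.4, mu = 0.001, G = 14,
                         f0 = 1, adh_scale = 0.1, dx = 0.5, dt = 0.01,
                         t_end = 500) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (epsilon < 0) stop("epsilon must be non-negative")
  if (dx <= 0 || dt <= 0) stop("dx and dt must be positive")
  bound <- 0.2 * dx^2 / max(D_rho, D_p, 1)
  if (dt > bound) {
    stop(sprintf(
      "dt = %g exceeds the explicit-Euler stability guard %g = 0.2 dx^2 / max(D_rho, D_p, 1)",
      dt, bound))
  }
  p <- list(D_rho = D_rho, D_phi = D_phi, D_psi = D_psi, D_p = D_p,
            alpha = alpha, kappa = kappa, lambda = lambda,
            tau1_inv = tau1_inv, T_memb = T_memb, beta = beta,
            epsilon = epsilon, sigma = sigma, gamma = gamma, theta = theta,
            mu = mu, G = G, f0 = f0, f0T = f0 * T_memb,
            adh_scale = adh_scale,
            dx = dx, dt = dt, t_end = t_end)
  class(p) <- "pf_params"
  p
}

#' @export
print.pf_params <- function(x, ...) {
  cat("<pf_params>\n")
  nm <- setdiff(names(x), "f0T")
  cat(paste(sprintf("  %-8s %g", nm, unlist(x[nm])), collapse = "\n"), "\n")
  invisible(x)
}

# Seconds represented by `t` nondimensional time units (1 unit = 10 s).
#' Convert nondimensional time to seconds
#'
#' The model time scale is set by the actin depolymerization rate:
#' one nondimensional unit corresponds to 10 s, so the standard 500-unit
#' run represents 5000 s.
#'
#' @param t nondimensional time.
#' @return Time in seconds.
#' @export
time_to_seconds <- function(t) 10 * t
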