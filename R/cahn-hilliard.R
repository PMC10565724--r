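# 3D wavenumber-squared array for a periodic cube of n voxels, spacing h.
ch_k2 <- function(n, h = 1) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * (2 * pi / (n * h))
  k2x <- f^2
  outer(outer(k2x, k2x, `+`), k2x, `+`)
}

#' Spinodal microstructure via the Cahn-Hilliard equation
#'
#' Evolves a conserved order parameter `u` from small-amplitude zero-mean
#' noise under `du/dt = lap(u^3 - u - eps2 lap u)` (symmetric 50:50 quench,
#' interface width ~2 voxels), using a stabilized semi-implicit spectral
#' update on a periodic cube. Phase separation forms bicontinuous domains
#' that coarsen; the run stops once the characteristic domain size reaches
#' `stop_size`, and `u > 0` is thresholded into the binary solid mask of a
#' bijel-templated material. Only the stop-time domain size matters
#' downstream; the mobility and quench details set the route, not the
#' endpoint morphology class.
#'
#' @param n cube edge in voxels at spacing 1 (default 64).
#' @param seed integer seed for the initial noise.
#' @param stop_size target characteristic domain size in um (at least 4).
#' @param eps2 square gradient coefficient (default 1).
#' @param dt_max late-stage time step (default 2; the first spinodal stage
#'   uses a smaller step).
#' @param max_steps hard cap on update steps.
#' @param check_every steps between domain-size evaluations.
#' @return A list: `mask` (binary solid), `u` (final field), `L` (domain
#'   size, um), `t`, `steps`, `seed`.
#' @export
cahn_hilliard_run <- function(n = 64, seed = 1, stop_size = 30, eps2 = 1,
                              dt_max = 2, max_steps = 20000,
                              check_every = 25) {
  if (stop_size < 4) stop("stop_size must be at least 4 voxels")
  set.seed(seed)
  u <- array(runif(n^3, -0.05, 0.05), dim = c(n, n, n))
  u <- u - mean(u)
  k2 <- ch_k2(n)
  k4 <- k2^2
  A <- 2 # stabilization constant (>= max f''/2 on the relevant range)
  uh <- fft(u)
  t <- 0; step <- 0
  L <- characteristic_domain_size(u, 1)
  L_hist <- c()
  repeat {
    dt <- if (t < 10) 0.1 else dt_max
    Nh <- fft(u^3 - u)
    uh <- (uh * (1 + dt * A * k2) - dt * k2 * Nh) /
      (1 + dt * A * k2 + dt * eps2 * k4)
    u <- Re(fft(uh, inverse = TRUE)) / n^3
    t <- t + dt; step <- step + 1
    if (step %% check_every == 0) {
      L <- characteristic_domain_size(u, 1)
      L_hist <- c(L_hist, L)
      if (L >= stop_size) break
      nh <- length(L_hist)
      stall_win <- ceiling(500 / check_every)
      if (nh > stall_win &&
          L_hist[nh] < 1.01 * L_hist[nh - stall_win]) {
        stop(sprintf("coarsening stalled at domain size %.2f um", L))
      }
    }
    if (step >= max_steps) {
      stop(sprintf("domain size %.2f um did not reach %g um in %d steps",
                   L, stop_size, max_steps))
    }
  }
  list(mask = array(as.numeric(u > 0), dim = dim(u)), u = u, L = L,
       L_history = L_hist, t = t, steps = step, seed = seed)
}

#' Characteristic domain size from the structure factor
#'
#' First-moment length of the radially collected structure factor of a
#' zero-mean field: `L = 2 pi sum(S) / sum(k S)` with `S(k) = |u_hat(k)|^2`
#' and the k = 0 mode excluded. For a single mode `sin(2 pi x / lambda)`
#' this returns the wavelength `lambda`; for a spinodal structure it is the
#' full (solid + void) period, so the single-phase domain width is about
#' half of it. Invariant under `u -> -u`.
#'
#' @param u 3D array (approximately zero mean).
#' @param spacing voxel spacing in um (default 1).
#' @return Characteristic length in um.
#' @export
characteristic_domain_size <- function(u, spacing = 1) {
  check_field(u)
  d <- dim(u)
  S <- Mod(fft(u - mean(u)))^2
  kax <- function(n) c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) *
    (2 * pi / (n * spacing))
  kmag <- sqrt(outer(outer(kax(d[1])^2, kax(d[2])^2, `+`), kax(d[3])^2, `+`))
  sel <- kmag > 0
  2 * pi * sum(S[sel]) / sum(kmag[sel] * S[sel])
}

#' Wrap a Cahn-Hilliard mask as a substrate
#'
#' Relaxes the spinodal solid mask into Phi and Psi. The top `open_above`
#' um of the domain can be cleared so a cell can be seeded above the porous
#' structure and migrate into it through the curved internal surfaces.
#'
#' @param ch result of [cahn_hilliard_run()].
#' @param grid simulation [grid_spec()] (extent must match the mask).
#' @param open_above clear the solid above this height (um); `Inf` keeps
#'   the full structure.
#' @param kappa adhesion (default 1).
#' @return A `pf_substrate`.
#' @export
make_btm <- function(ch, grid, open_above = Inf, kappa = 1) {
  mask <- ch$mask
  if (is.finite(open_above)) {
    z <- axis_coords(dim(mask)[3], 1)
    mask[, , z > open_above] <- 0
  }
  build_substrate(mask, grid, kappa,
                  meta = list(kind = "btm", L = ch$L, seed = ch$seed,
                              open_above = open_above))
}
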