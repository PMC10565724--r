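#' Run a cell-substrate simulation
#'
#' Integrates the coupled rho / p dynamics from a `pf_cell` initial state,
#' recording shape metrics at a fixed cadence and (optionally) field
#' snapshots. The model is deterministic: identical inputs give identical
#' trajectories. A run terminates early at steady state, defined as no
#' measurable movement or shape change for `steady_hold` consecutive
#' recording intervals (centroid motion below `steady_disp` um per time
#' unit and `max |drho/dt|` below `steady_drho`).
#'
#' @param state a `pf_cell` (its `A0` must be set, e.g. from
#'   [free_cell_reference()]).
#' @param substrate substrate object or `NULL` for free space.
#' @param params a [model_params()] (its `dx` must match the grid spacing).
#' @param t_end total nondimensional time (default `params$t_end`).
#' @param metric_every recording cadence in time units (default 1).
#' @param store_every snapshot cadence in time units (`Inf` = only final).
#' @param steady_stop stop at steady state (default TRUE).
#' @param steady_disp,steady_drho,steady_hold steady-state thresholds: see
#'   Description. Defaults 1e-3 um per unit, 1e-4 per unit, 10 intervals.
#' @param refresh_every active-band refresh interval in integrator steps.
#' @param verbose print progress.
#' @return A `pf_trajectory`: list with `metrics` (data frame), `snapshots`
#'   (list of `list(t, rho, p)`), `final_state`, `steady`
#'   (`list(reached, t)`), `params`, `substrate_meta`, `grid`.
#' @export
simulate_cell <- function(state, substrate, params, t_end = params$t_end,
                          metric_every = 1, store_every = Inf,
                          steady_stop = TRUE, steady_disp = 1e-3,
                          steady_drho = 1e-4, steady_hold = 10,
                          refresh_every = 10, verbose = FALSE) {
  if (is.na(state$A0)) stop("state$A0 is not set; run free_cell_reference()")
  if (abs(params$dx - state$grid$spacing) > 1e-12) {
    stop("params$dx does not match the grid spacing")
  }
  pre <- substrate_precompute(substrate, state$grid)
  rows <- list()
  snaps <- list()
  measure <- function(st, drho_rate, n_active) {
    ctr <- cell_centroid(st$rho, st$grid)
    k <- inertia_eigenvalues(st$rho, st$grid)
    E <- shape_energy(st$rho, substrate, params, st$grid)
    ca <- if (is.null(substrate)) 0 else
      contact_area(st$rho, substrate, st$grid, params$G)
    data.frame(t = st$t, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               V = cell_volume(st$rho, st$grid),
               A = surface_area(st$rho, st$grid),
               k11 = k[1], k22 = k[2], k33 = k[3],
               E_shape = E, mean_pz = mean_pz(st$p, st$rho),
               contact_area = ca, max_drho_rate = drho_rate,
               n_active = n_active, row.names = NULL)
  }
  rows[[1]] <- measure(state, NA_real_, NA_integer_)
  if (is.finite(store_every)) {
    snaps[[1]] <- list(t = state$t, rho = state$rho, p = state$p)
  }
  hold <- 0L
  steady <- list(reached = FALSE, t = NA_real_)
  t0 <- state$t
  nblocks <- ceiling((t_end - t0) / metric_every - 1e-9)
  for (b in seq_len(max(nblocks, 0))) {
    span <- min(metric_every, t_end - state$t)
    if (span <= 0) break
    prev_ctr <- c(rows[[length(rows)]]$cx, rows[[length(rows)]]$cy,
                  rows[[length(rows)]]$cz)
    state <- advance_cell(state, pre, params, span,
                          refresh_every = refresh_every)
    dg <- attr(state, "diag")
    drho_rate <- dg$max_drho / params$dt
    row <- measure(state, drho_rate, dg$n_active)
    rows[[length(rows) + 1]] <- row
    if (is.finite(store_every) &&
        (state$t - t0) %% store_every < metric_every - 1e-9) {
      snaps[[length(snaps) + 1]] <- list(t = state$t, rho = state$rho,
                                         p = state$p)
    }
    if (verbose && b %% 25 == 0) {
      message(sprintf("t = %6.1f  z_cm = %6.2f  A = %7.1f  pz = %+.3f",
                      state$t, row$cz, row$A, row$mean_pz))
    }
    disp_rate <- sqrt(sum((c(row$cx, row$cy, row$cz) - prev_ctr)^2)) / span
    if (disp_rate < steady_disp && drho_rate < steady_drho) {
      hold <- hold + 1L
    } else hold <- 0L
    if (steady_stop && hold >= steady_hold) {
      steady <- list(reached = TRUE, t = state$t)
      break
    }
  }
  snaps[[length(snaps) + 1]] <- list(t = state$t, rho = state$rho,
                                     p = state$p)
  structure(list(metrics = do.call(rbind, rows), snapshots = snaps,
                 final_state = state, steady = steady, params = params,
                 substrate_meta = if (is.null(substrate)) NULL
                                  else substrate$meta,
                 grid = state$grid),
            class = "pf_trajectory")
}

#' @export
print.pf_trajectory <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<pf_trajectory %d records, t in [%g, %g]%s>\n",
              nrow(m), min(m$t), max(m$t),
              if (x$steady$reached)
                sprintf(", steady at t = %g", x$steady$t) else ""))
  invisible(x)
}
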