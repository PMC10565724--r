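#' Canonical study scenarios
#'
#' Builders for the miniature study geometries used throughout the tests
#' and the validation suite. Each returns the substrate, an initial cell
#' state with its free-cell reference area attached, the parameter set and
#' a default run length.
#'
#' All scenarios run at spacing 1 with `dt = 0.04` and a wide membrane
#' indicator (`G = 4`): on a spacing-1 lattice the interface spans ~3
#' voxels, and a membrane band of that width (rather than the razor-thin
#' `G = 14` band appropriate at spacing 0.5) is what makes the
#' membrane-tension term act on the whole diffuse membrane. With it the
#' model supports sustained crawling at physiologic speed.
#'
#' Geometries:
#' * `hemisphere`: 64 x 64 x 48 box, a 12 um hemispherical bump on a flat
#'   base; a 17 um cube cell starts just above the apex, 2 um off-axis
#'   (some lateral offset is needed to break the exact mirror symmetry of
#'   the discretized problem; the outcome is not sensitive to its size).
#' * `strip`: flat surface with a centred adhesive strip (kappa = 5 on,
#'   1 off) of the requested width.
#' * `ptm3`: vertical three-pore interconnect motif, 42 um pores with
#'   0.325-diameter windows (13.65 um), interrogated by a 7 um-radius
#'   spherical cell — preserving the study's window/cell diameter ratio of
#'   about one, the ratio that controls interconnect interrogation. The
#'   cell starts in the middle pocket with its leading edge ~4 um above
#'   the lower window.
#' * `hyperboloid`: channel with the same maximum/minimum diameters as
#'   `ptm3` but low-curvature hyperboloid walls; the cell starts above the
#'   throat, as close as the geometry allows.
#' * `btm`: a 64^3 spinodal (bijel-templated) structure with ~30 um
#'   domains, open above; the cell starts above the porous bulk and
#'   migrates in through the saddle-curved internal surfaces.
#'
#' @param epsilon membrane tension weight (default 0.34; 0 disables the
#'   tension term).
#' @param strip_width strip width in um (scenario `strip`).
#' @param seed seed for the spinodal generator (scenario `btm`).
#' @param dx lattice spacing (default 1).
#' @param dt time step (default 0.02 at spacing 1).
#' @param G membrane indicator steepness (default 4 at spacing 1).
#' @return A list with `substrate`, `state`, `params`, `t_end`, `name`.
#' @export
scenario_hemisphere <- function(epsilon = 0.34, dx = 1, dt = 0.04, G = 4) {
  params <- model_params(epsilon = epsilon, dx = dx, dt = dt, G = G)
  g <- grid_spec(round(c(64, 64, 48) / dx), dx)
  sub <- make_hemisphere_array(g, radius = 12, pitch = 32, base_height = 4)
  apex <- sub$meta$apex
  ref <- free_cell_reference(params)
  st <- initialize_cell(g, c(apex[1] + 2, apex[2], apex[3] + 10.5),
                        edge = 17, substrate = sub, A0 = ref$A0)
  list(substrate = sub, state = st, params = params, t_end = 100,
       name = sprintf("hemisphere_eps%g", epsilon))
}

#' @rdname scenario_hemisphere
#' @export
scenario_strip <- function(strip_width = 20, dx = 1, dt = 0.04, G = 4) {
  params <- model_params(dx = dx, dt = dt, G = G)
  g <- grid_spec(round(c(64, 64, 32) / dx), dx)
  sub <- make_flat_with_strip(g, strip_width = strip_width, base_height = 4)
  ref <- free_cell_reference(params)
  ext <- g$shape * dx
  st <- initialize_cell(g, c(ext[1] / 2, ext[2] / 2, 4 + 2 + 8.5),
                        edge = 17, substrate = sub, A0 = ref$A0)
  list(substrate = sub, state = st, params = params, t_end = 120,
       name = sprintf("strip_w%g", strip_width))
}

#' @rdname scenario_hemisphere
#' @export
scenario_ptm_interconnect <- function(epsilon = 0.34, dx = 1, dt = 0.04,
                                      G = 4) {
  params <- model_params(epsilon = epsilon, dx = dx, dt = dt, G = G)
  g <- grid_spec(round(c(52, 52, 104) / dx), dx)
  sub <- make_ptm_interconnect(g, sphere_diameter = 42,
                               interconnect_frac = 0.325)
  ref <- free_cell_reference(params, shape = "sphere", radius = 7)
  ctr <- sub$meta$centers[2, ]
  start <- c(ctr[1], ctr[2], sub$meta$window_z[1] + 7 + 4)
  st <- initialize_cell(g, start, shape = "sphere", radius = 7,
                        substrate = sub, A0 = ref$A0)
  list(substrate = sub, state = st, params = params, t_end = 300,
       name = "ptm_interconnect")
}

#' @rdname scenario_hemisphere
#' @export
scenario_hyperboloid <- function(epsilon = 0.34, dx = 1, dt = 0.04, G = 4) {
  params <- model_params(epsilon = epsilon, dx = dx, dt = dt, G = G)
  g <- grid_spec(round(c(52, 52, 104) / dx), dx)
  sub <- make_hyperboloid(g, d_max = 42, d_min = 0.325 * 42, length = 40)
  ref <- free_cell_reference(params, shape = "sphere", radius = 7)
  ext <- g$shape * dx
  st <- initialize_cell(g, c(ext[1] / 2, ext[2] / 2, 64),
                        shape = "sphere", radius = 7, substrate = sub,
                        A0 = ref$A0)
  list(substrate = sub, state = st, params = params, t_end = 300,
       name = "hyperboloid")
}

#' @rdname scenario_hemisphere
#' @export
scenario_btm <- function(seed = 7, epsilon = 0.34, dx = 1, dt = 0.04, G = 4) {
  params <- model_params(epsilon = epsilon, dx = dx, dt = dt, G = G)
  g <- grid_spec(round(c(64, 64, 64) / dx), dx)
  ch <- cahn_hilliard_run(n = 64, seed = seed, stop_size = 30)
  sub <- make_btm(ch, g, open_above = 44)
  ref <- free_cell_reference(params, shape = "sphere", radius = 7)
  ext <- g$shape * dx
  st <- initialize_cell(g, c(ext[1] / 2, ext[2] / 2, 53),
                        shape = "sphere", radius = 7, substrate = sub,
                        A0 = ref$A0)
  list(substrate = sub, state = st, params = params, t_end = 150,
       name = sprintf("btm_seed%d", seed))
}

#' Run a canonical scenario
#'
#' Convenience wrapper: builds the scenario and integrates it with metric
#' recording every time unit. Results for a given scenario name and
#' arguments are cached for the session (the model is deterministic, so a
#' cached trajectory is identical to a fresh one).
#'
#' @param scenario one of `"hemisphere"`, `"strip"`, `"ptm3"`,
#'   `"hyperboloid"`, `"btm"`.
#' @param ... passed to the scenario builder.
#' @param t_end override the scenario's default run length.
#' @param cache reuse a session-cached result if available (default TRUE).
#' @param verbose print progress.
#' @return A `pf_trajectory` (with the scenario attached as attribute
#'   `"scenario"`).
#' @export
run_scenario <- function(scenario = c("hemisphere", "strip", "ptm3",
                                      "hyperboloid", "btm"),
                         ..., t_end = NULL, cache = TRUE, verbose = FALSE) {
  scenario <- match.arg(scenario)
  args <- list(...)
  key <- paste0("scenario|", scenario, "|",
                paste(names(args), unlist(args), sep = "=", collapse = ","),
                "|", if (is.null(t_end)) "default" else t_end)
  if (cache && !is.null(.pf_cache[[key]])) return(.pf_cache[[key]])
  sc <- switch(scenario,
               hemisphere = do.call(scenario_hemisphere, args),
               strip = do.call(scenario_strip, args),
               ptm3 = do.call(scenario_ptm_interconnect, args),
               hyperboloid = do.call(scenario_hyperboloid, args),
               btm = do.call(scenario_btm, args))
  tr <- simulate_cell(sc$state, sc$substrate, sc$params,
                      t_end = if (is.null(t_end)) sc$t_end else t_end,
                      verbose = verbose)
  attr(tr, "scenario") <- sc
  if (cache) .pf_cache[[key]] <- tr
  tr
}
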