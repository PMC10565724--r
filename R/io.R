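# Tiny rolling hash for manifests / checkpoints (no external digest needed).
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Serialize a field with its grid metadata
#'
#' Fields are stored as portable RDS containers carrying the array, the
#' grid shape and spacing and a field name, mirroring the layout of a
#' self-describing array store.
#'
#' @param f 3D or 4D array.
#' @param grid grid or spacing.
#' @param file output path.
#' @param name field name recorded in the container.
#' @export
save_field <- function(f, grid, file, name = "field") {
  obj <- list(name = name, shape = dim(f), spacing = as_spacing(grid),
              values = f)
  tmp <- paste0(file, ".tmp")
  saveRDS(obj, tmp)
  file.rename(tmp, file)
  invisible(file)
}

#' @rdname save_field
#' @export
load_field <- function(file) readRDS(file)

#' Write a run checkpoint
#'
#' A checkpoint holds the full cell state, the substrate, the parameters
#' and a config hash; [resume_run()] continues the trajectory identically
#' to an uninterrupted run (the integrator is deterministic).
#'
#' @param state a `pf_cell`.
#' @param substrate substrate or `NULL`.
#' @param params a [model_params()].
#' @param file checkpoint path.
#' @export
save_checkpoint <- function(state, substrate, params, file) {
  obj <- list(state = state, substrate = substrate, params = params,
              t = state$t,
              config_hash = fnv1a(list(params, state$V0, state$A0)))
  tmp <- paste0(file, ".tmp")
  saveRDS(obj, tmp)
  file.rename(tmp, file)
  invisible(file)
}

#' Resume a run from a checkpoint
#'
#' @param file checkpoint path (from [save_checkpoint()]).
#' @param t_end total time to integrate to (absolute, continuing the
#'   checkpointed clock).
#' @param ... passed to [simulate_cell()].
#' @return A `pf_trajectory`.
#' @export
resume_run <- function(file, t_end, ...) {
  ck <- readRDS(file)
  simulate_cell(ck$state, ck$substrate, ck$params, t_end = t_end, ...)
}

#' Run manifest
#'
#' The reproducibility record of a run: full parameter set, substrate
#' metadata and seed, package version, termination reason, and the
#' dimensional duration (1 time unit = 10 s, so the standard 500-unit run
#' is 5000 s). Wall-clock metadata is informational only.
#'
#' @param traj a `pf_trajectory`.
#' @param config the run configuration list (optional).
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(traj, config = NULL) {
  m <- traj$metrics
  t_total <- max(m$t) - min(m$t)
  list(
    package_version = as.character(utils::packageVersion("phasecell")),
    config_hash = fnv1a(list(config, unclass(traj$params))),
    params = unclass(traj$params)[setdiff(names(traj$params), "f0T")],
    substrate = traj$substrate_meta,
    grid = list(shape = traj$grid$shape, spacing = traj$grid$spacing),
    t_total = t_total,
    duration_seconds = time_to_seconds(t_total),
    termination = if (traj$steady$reached)
      sprintf("steady state at t = %g", traj$steady$t) else "t_end reached",
    steady = traj$steady,
    wall = list(generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
}

# ---- run configuration files (key = value schema) ----

#' Read a run configuration file
#'
#' Plain-text `key = value` lines (`#` comments allowed). Recognized keys:
#' `scenario` (hemisphere | strip | ptm3 | hyperboloid | btm), scenario
#' options (`epsilon`, `strip_width`, `seed`, `dx`, `dt`), `t_end`,
#' `metric_every`, `store_every`, and `out_dir`. Values are parsed as
#' numbers where possible.
#'
#' @param file path.
#' @return Named list.
#' @export
read_run_config <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(out) <- keys
  out
}

#' Run a simulation from a configuration
#'
#' Executes the configured scenario and writes the standard artifact set
#' to `out_dir`: `metrics.csv` (shape metrics time series), `manifest.json`
#' (reproducibility record), `final.stl` (final rho = 0.5 surface),
#' `checkpoint.rds` and `final_rho.rds`. All writes are atomic
#' (temp + rename). Identical configurations produce identical metrics.
#'
#' @param config path to a config file or a named list
#'   (see [read_run_config()]).
#' @param verbose print progress.
#' @return The `pf_trajectory`, invisibly.
#' @export
run_simulation <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$scenario)) stop("config must name a scenario")
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  builder_args <- config[intersect(names(config),
                                   c("epsilon", "strip_width", "seed",
                                     "dx", "dt"))]
  sim_args <- config[intersect(names(config),
                               c("t_end", "metric_every", "store_every"))]
  tr <- do.call(run_scenario,
                c(list(scenario = config$scenario, cache = FALSE,
                       verbose = verbose),
                  builder_args, sim_args))
  write_metrics <- function(m, path) {
    tmp <- paste0(path, ".tmp")
    utils::write.csv(m, tmp, row.names = FALSE)
    file.rename(tmp, path)
  }
  write_metrics(tr$metrics, file.path(out_dir, "metrics.csv"))
  man <- run_manifest(tr, config)
  tmp <- file.path(out_dir, "manifest.json.tmp")
  jsonlite::write_json(man, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
  export_stl(tr$final_state$rho, file.path(out_dir, "final.stl"),
             grid = tr$grid)
  sc <- attr(tr, "scenario")
  save_checkpoint(tr$final_state, sc$substrate, sc$params,
                  file.path(out_dir, "checkpoint.rds"))
  save_field(tr$final_state$rho, tr$grid,
             file.path(out_dir, "final_rho.rds"), name = "rho")
  invisible(tr)
}

#' Recompute the metrics series from stored snapshots
#'
#' Analysis is decoupled from simulation: given a trajectory's snapshots
#' (or a snapshot list), this recomputes the same metrics the run recorded
#' in-flight; on identical fields the result is identical.
#'
#' @param traj a `pf_trajectory` run with a finite `store_every`.
#' @param substrate substrate used for the run (or `NULL`).
#' @param params a [model_params()].
#' @return Data frame of metrics, one row per snapshot.
#' @export
recompute_metrics <- function(traj, substrate = NULL, params = NULL) {
  if (is.null(params)) params <- traj$params
  grid <- traj$grid
  rows <- lapply(traj$snapshots, function(sn) {
    ctr <- cell_centroid(sn$rho, grid)
    k <- inertia_eigenvalues(sn$rho, grid)
    data.frame(t = sn$t, cx = ctr[1], cy = ctr[2], cz = ctr[3],
               V = cell_volume(sn$rho, grid),
               A = surface_area(sn$rho, grid),
               k11 = k[1], k22 = k[2], k33 = k[3],
               E_shape = shape_energy(sn$rho, substrate, params, grid),
               mean_pz = mean_pz(sn$p, sn$rho),
               contact_area = if (is.null(substrate)) 0 else
                 contact_area(sn$rho, substrate, grid, params$G),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
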