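#' Deterministic miniature fixtures of every study scenario
#'
#' Builds the substrates and initial cell states of all canonical
#' scenarios at desk scale (grids of at most 64^3): the hemisphere array,
#' the 20 um adhesive strip, the three-pore interconnect motif (24 um
#' pores), the matched hyperboloid channel, and a 64^3 spinodal structure.
#' Everything is generated in code; the same seed always reproduces the
#' same set (only the spinodal generator consumes randomness).
#'
#' @param seed integer seed (drives the spinodal structure).
#' @param include_btm build the spinodal fixture too (the slowest one;
#'   default TRUE).
#' @return Named list of scenario lists (`substrate`, `state`, `params`,
#'   `t_end`, `name`).
#' @export
fixture_suite <- function(seed = 7, include_btm = TRUE) {
  out <- list(
    hemisphere = scenario_hemisphere(),
    strip20 = scenario_strip(20),
    ptm3 = scenario_ptm_interconnect(),
    hyperboloid = scenario_hyperboloid()
  )
  if (include_btm) out$btm <- scenario_btm(seed = seed)
  out
}

# Measured window diameter of the three-pore motif: pore area of the mask
# slice just above the lower window plane, corrected to the plane with the
# spherical pore profile r^2(z) = R^2 - (z_c - z)^2.
ptm3_window_diameter <- function(substrate) {
  wz <- substrate$meta$window_z[1]
  zc <- substrate$meta$centers[2, 3]    # middle pocket centre
  k <- ceiling(wz + 0.5)                # slice centre just above the plane
  zs <- k - 0.5
  area <- sum(substrate$mask[, , k] == 0)
  r2 <- area / pi + (zc - zs)^2 - (zc - wz)^2
  2 * sqrt(max(r2, 0))
}
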