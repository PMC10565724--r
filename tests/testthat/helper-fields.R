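# shared fixture builders (everything generated in code)

ax <- function(n, h) (seq_len(n) - 0.5) * h

# diffuse (tanh) sphere of radius R and interface width w on an n^3 grid
tanh_sphere <- function(n = 48, h = 0.5, R = 8, w = 1, center = NULL) {
  if (is.null(center)) center <- rep(n * h / 2, 3)
  x <- ax(n, h)
  r <- sqrt(outer(outer((x - center[1])^2, (x - center[2])^2, `+`),
                  (x - center[3])^2, `+`))
  0.5 * (1 - tanh((r - R) / w))
}

# tanh slab interface normal to z at height z0
tanh_slab <- function(n = 24, h = 0.5, z0 = NULL, w = 1) {
  if (is.null(z0)) z0 <- n * h / 2
  z <- ax(n, h)
  prof <- 0.5 * (1 - tanh((z - z0) / w))
  array(rep(prof, each = n * n), dim = c(n, n, n))
}

# infinite cylinder along z, radius R
tanh_cylinder <- function(n = 48, h = 0.5, R = 8, w = 1) {
  x <- ax(n, h); c0 <- n * h / 2
  r2d <- sqrt(outer((x - c0)^2, (x - c0)^2, `+`))
  prof <- 0.5 * (1 - tanh((r2d - R) / w))
  array(rep(prof, times = n), dim = c(n, n, n))
}

# flat slab substrate of thickness `base` on an arbitrary grid
slab_substrate <- function(grid, base = 4, kappa = 1) {
  n1 <- round(grid$shape * grid$spacing)
  mask <- array(0, dim = n1)
  z1 <- ax(n1[3], 1)
  mask[, , z1 <= base] <- 1
  phasecell:::build_substrate(mask, grid, kappa = kappa,
                              meta = list(kind = "flat-slab", base = base))
}

# spacing-1 parameters used by the scenario-scale tests
params1 <- function(...) model_params(dx = 1, dt = 0.02, G = 4, ...)

# small spinodal run shared by several substrate tests (computed once)
get_ch48 <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) memo <<- cahn_hilliard_run(n = 48, seed = 3,
                                                  stop_size = 12)
    memo
  }
})
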