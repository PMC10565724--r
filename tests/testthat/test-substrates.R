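# substrate generators: relaxation, geometry oracles, packing, spinodal

test_that("mask relaxation conserves mass and widens Psi beyond Phi", {
  n <- c(24, 24, 24)
  mask <- array(0, dim = n)
  mask[, , 1:8] <- 1
  expect_error(relax_substrate(mask * 0.5), "binary")
  phi <- relax_substrate(mask, "phi")
  psi <- relax_substrate(mask, "psi")
  expect_lt(abs(sum(phi) - sum(mask)) / sum(mask), 1e-10)
  expect_lt(abs(sum(psi) - sum(mask)) / sum(mask), 1e-10)
  # uniform field is a diffusion fixed point
  ones <- array(1, dim = n)
  expect_equal(relax_substrate(ones, "phi"), ones)
  # half-width of the 0.1 contour above the slab edge: Psi strictly wider
  prof_phi <- phi[12, 12, ]
  prof_psi <- psi[12, 12, ]
  z <- ax(24, 1)
  reach <- function(prof) max(z[prof > 0.1]) # highest point sensing the slab
  expect_gt(reach(prof_psi), reach(prof_phi))
  # the assembled substrate satisfies Psi >= Phi pointwise and both in [0,1]
  g <- grid_spec(n, 1)
  sub <- phasecell:::build_substrate(mask, g)
  expect_true(all(sub$psi >= sub$phi - 1e-6))
  expect_true(all(sub$phi >= 0 & sub$phi <= 1))
  expect_true(all(sub$psi >= 0 & sub$psi <= 1))
})

test_that("adhesive strip has exact widths and kappa values", {
  g <- grid_spec(c(64, 64, 32), 1)
  sub <- make_flat_with_strip(g, strip_width = 20)
  expect_setequal(unique(as.numeric(sub$kappa)), c(1, 5))
  n_on <- sum(sub$kappa[, 1, 1] == 5)
  expect_lt(abs(n_on * g$spacing - 20), 1.5)  # +-1 voxel row
  # strip runs the full length of the surface
  expect_true(all(apply(sub$kappa == 5, 2, sum) == n_on * g$shape[3]))
  expect_error(make_flat_with_strip(g, strip_width = -2), "positive")
})

test_that("hemisphere array matches its analytic solid volume", {
  g <- grid_spec(c(64, 64, 48), 1)
  sub <- make_hemisphere_array(g, radius = 12, pitch = 32, base_height = 4)
  # apex height: base + radius
  ztop <- max(which(apply(sub$mask == 1, 3, any)))
  expect_equal(ztop, 16)
  # analytic volume: base slab + bumps (central + 4 edge-truncated halves)
  vol <- sum(sub$mask)
  base_vol <- 64 * 64 * 4
  bump_vol <- (2 / 3) * pi * 12^3
  # bumps at (32,32), 4 at edge midpoints (half in box), 4 corners (quarter)
  expected <- base_vol + bump_vol * (1 + 4 * 0.5 + 4 * 0.25)
  expect_lt(abs(vol - expected) / expected, 0.03)
})

test_that("layered packing respects its overlap floor and density window", {
  pk <- pack_spheres_rcp(radius = 35, box = c(280, 280, 280), seed = 11,
                         min_fraction = 0.3)
  d <- as.matrix(dist(pk$centers))
  diag(d) <- Inf
  # periodic images in x/y do not matter for the minimum since violations
  # would be caught by the generator itself; check the direct distances
  expect_gt(min(d), 2 * 35 * (1 - 0.35))
  expect_gt(pk$fraction, 0.55)
  expect_lt(pk$fraction, 0.75)
  # voxel estimate agrees with the Monte-Carlo oracle
  mc <- packing_fraction(pk, "mc", n_points = 2e5, seed = 3)
  expect_lt(abs(mc - packing_fraction(pk, "voxel")), 0.005)
  # deterministic given the seed
  pk2 <- pack_spheres_rcp(radius = 35, box = c(280, 280, 280), seed = 11,
                          min_fraction = 0.3)
  expect_identical(pk$centers, pk2$centers)
})

test_that("inversion geometry: window diameter follows sphere intersection", {
  # two overlapping spheres: window = 2 r sqrt(1 - (1-ov)^2)
  r <- 10; ov <- 0.325
  centers <- rbind(c(20, 20, 14), c(20, 20, 14 + 2 * r * (1 - ov)))
  pk <- structure(list(centers = centers, radius = r,
                       box = c(40, 40, 42), seed = 1, fraction = NA,
                       meta = list()), class = "pf_packing")
  g <- grid_spec(c(40, 40, 42), 1)
  sub <- make_ptm(pk, g)
  # solid is the exact complement of the voxelized pore union
  pore_frac <- 1 - mean(sub$mask)
  expect_gt(pore_frac, 0)
  # pore slice area at the window plane gives the window diameter
  zw <- 14 + r * (1 - ov)
  k <- round(zw + 0.5)
  a <- sum(sub$mask[, , k] == 0)
  d_meas <- 2 * sqrt(a / pi)
  d_true <- 2 * r * sqrt(1 - (1 - ov)^2)
  expect_lt(abs(d_meas - d_true) / d_true, 0.05)
})

test_that("pore space of a small inverted packing is connected", {
  set.seed(1)
  pk <- pack_spheres_rcp(radius = 12, box = c(96, 96, 96), seed = 5,
                         min_fraction = 0.3)
  g <- grid_spec(c(72, 72, 72), 1)
  sub <- make_ptm(pk, g)
  pore <- sub$mask == 0
  idx <- which(pore)
  kk <- arrayInd(idx, dim(pore))[, 3]
  seeds <- idx[kk == 1 | kk == 72]
  reach <- phasecell:::cpp_flood6(array(pore, dim(pore)), as.integer(seeds))
  expect_gt(mean(reach[pore]), 0.99)
})

test_that("three-pore interconnect has the printed window fraction and symmetry", {
  g <- grid_spec(c(52, 52, 104), 1)
  sub <- make_ptm_interconnect(g, sphere_diameter = 42,
                               interconnect_frac = 0.325)
  d_meas <- phasecell:::ptm3_window_diameter(sub)
  expect_lt(abs(d_meas / 42 - 0.325), 0.03)
  # four-fold symmetry about z
  rot90 <- aperm(sub$mask[, rev(seq_len(52)), ], c(2, 1, 3))
  expect_identical(rot90, sub$mask)
  # pore cross-section is minimal at the window planes
  area <- apply(sub$mask == 0, 3, sum)
  zin <- which(area > 0)
  wz <- round(sub$meta$window_z + 0.5)
  interior <- setdiff(seq(min(wz), max(wz)), wz)
  expect_lt(max(area[wz]), min(area[interior]))
  expect_error(make_ptm_interconnect(g, 42, interconnect_frac = 0.7),
               "interconnect_frac")
})

test_that("hyperboloid channel has its throat at mid-plane with low curvature", {
  g <- grid_spec(c(52, 52, 104), 1)
  sub <- make_hyperboloid(g, d_max = 42, d_min = 13.65, length = 40)
  area <- apply(sub$mask == 0, 3, sum)
  z0 <- round(sub$meta$throat_z)
  d_mid <- 2 * sqrt(area[z0] / pi)
  expect_lt(abs(d_mid - 13.65), 2)       # +-1 voxel on the diameter
  # the diameter profile is minimal at the throat and convex around it
  chan <- (z0 - 18):(z0 + 18)
  expect_equal(which.min(area[chan]), 19, tolerance = 1)
  expect_true(all(diff(area[(z0):(z0 + 18)]) >= 0))
  expect_true(all(diff(area[(z0 - 18):(z0)]) <= 0))
  # wall curvature at the throat is milder than at the matching PTM rim
  ptm <- make_ptm_interconnect(g, sphere_diameter = 42,
                               interconnect_frac = 0.325)
  c_hyp <- interface_curvature(sub$phi, g)
  c_ptm <- interface_curvature(ptm$phi, g)
  at_wall <- function(phi, cc, kplane) {
    gr <- fd_gradient(phi, g)
    gn <- sqrt(gr[, , kplane, 1]^2 + gr[, , kplane, 2]^2 +
                 gr[, , kplane, 3]^2)
    sel <- gn > 0.2   # wall shell on that plane
    mean(abs(cc[, , kplane][sel]))
  }
  k_hyp <- round(sub$meta$throat_z)
  k_ptm <- round(ptm$meta$window_z[1] + 0.5)
  expect_lt(at_wall(sub$phi, c_hyp, k_hyp), at_wall(ptm$phi, c_ptm, k_ptm))
  expect_error(make_hyperboloid(g, d_max = 10, d_min = 12), "smaller")
})

test_that("spinodal generator conserves the mean and separates both phases", {
  ch <- get_ch48()
  expect_lt(abs(mean(ch$u)), 1e-8)
  expect_lt(abs(mean(ch$mask) - 0.5), 0.05)
  # bicontinuity: both phases percolate along z
  perc <- function(mask) {
    idx <- which(mask)
    kk <- arrayInd(idx, dim(mask))[, 3]
    seeds <- idx[kk == 1]
    reach <- phasecell:::cpp_flood6(array(mask, dim(mask)),
                                    as.integer(seeds))
    any(reach[, , dim(mask)[3]])
  }
  expect_true(perc(ch$mask == 1))
  expect_true(perc(ch$mask == 0))
  # domain size grows monotonically after the spinodal transient
  Lh <- ch$L_history
  expect_true(all(diff(Lh[-(1:2)]) > -0.2))
  expect_gte(ch$L, 12)
})

test_that("structure-factor length recovers a single-mode wavelength", {
  n <- 64
  x <- ax(n, 1)
  u <- array(rep(sin(2 * pi * x / 16), times = n * n), dim = c(n, n, n))
  L <- characteristic_domain_size(u, 1)
  expect_lt(abs(L - 16) / 16, 0.05)
  expect_equal(characteristic_domain_size(-u, 1), L)
})

test_that("spinodal surfaces are saddle-dominated (non-positive Gaussian K)", {
  ch <- get_ch48()
  # smooth the thresholded structure slightly and evaluate K on the surface
  g <- grid_spec(c(48, 48, 48), 1)
  phi <- relax_substrate(ch$mask, "psi")
  K <- implicit_gaussian_curvature(phi, g, grad_min = 0.05)
  sel <- abs(phi - 0.5) < 0.1 & !is.na(K)
  expect_gt(mean(K[sel] <= 1e-3), 0.8)
})
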