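# shape quantification against closed-form oracles

test_that("displacement is zero for a static series and exact for shifts", {
  m <- data.frame(t = 0:5, cx = 3, cy = 4, cz = 5)
  expect_equal(centroid_displacement(m)$r, rep(0, 6))
  g <- grid_spec(c(48, 48, 48), 0.5)
  f1 <- tanh_sphere(n = 48, h = 0.5, R = 6, center = c(12, 12, 12))
  f2 <- tanh_sphere(n = 48, h = 0.5, R = 6, center = c(12, 12, 13.5))
  c1 <- cell_centroid(f1, g); c2 <- cell_centroid(f2, g)
  expect_equal(sqrt(sum((c2 - c1)^2)), 1.5, tolerance = 1e-6)
})

test_that("centered-difference velocity is exact for linear and quadratic r", {
  t <- 0:10
  lin <- velocity_series(data.frame(t = t, r = 3 * t))
  expect_equal(lin$v, rep(3, 11))
  con <- velocity_series(data.frame(t = t, r = rep(2, 11)))
  expect_equal(con$v, rep(0, 11))
  quad <- velocity_series(data.frame(t = t, r = t^2))
  expect_equal(quad$v[2:10], 2 * t[2:10])  # interior exact for quadratics
  expect_error(velocity_series(data.frame(t = 0:1, r = 0:1)), "3 samples")
})

test_that("inertia eigenvalues classify balls and disks", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  ball <- tanh_sphere(n = 48, h = 0.5, R = 8)
  k <- inertia_eigenvalues(ball, g)
  expect_lt((k[1] - k[3]) / k[1], 0.02)
  # thin disk: axis moment twice the diametral moment
  disk <- array(0, dim = c(64, 64, 64))
  x <- ax(64, 0.5)
  r2 <- outer((x - 16)^2, (x - 16)^2, `+`)
  for (kz in which(abs(x - 16) <= 1)) disk[, , kz] <- (r2 <= 144) * 1
  kd <- inertia_eigenvalues(disk, grid_spec(c(64, 64, 64), 0.5))
  expect_lt(abs(kd[1] / kd[2] - 2), 0.1)
  expect_lt(kd[2] / kd[3] - 1, 0.05)
  expect_error(inertia_eigenvalues(disk * 0, g), "empty")
})

test_that("shape energy grows with area and ignores distant substrates", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  p <- model_params()
  small <- tanh_sphere(n = 48, h = 0.5, R = 6)
  large <- tanh_sphere(n = 48, h = 0.5, R = 9)
  expect_gt(shape_energy(large, NULL, p, g),
            shape_energy(small, NULL, p, g))
  # slab far below the cell: substrate term vanishes
  g1 <- grid_spec(c(32, 32, 32), 1)
  sub <- slab_substrate(g1, base = 3)
  cellf <- tanh_sphere(n = 32, h = 1, R = 5, center = c(16, 16, 24))
  E_sub <- shape_energy(cellf, sub, p, g1)
  E_free <- shape_energy(cellf, NULL, p, g1)
  expect_lt(abs(E_sub - E_free) / abs(E_free), 1e-3)
})

test_that("mean polarity is the rho-weighted z-average over the cell", {
  g <- grid_spec(c(16, 16, 16), 1)
  st <- initialize_cell(g, c(8, 8, 8), edge = 6, p_dir = c(0, 0, -1))
  expect_equal(mean_pz(st$p, st$rho), -1)
  st$p[] <- 0
  expect_equal(mean_pz(st$p, st$rho), 0)
})

test_that("projected aspect ratio recovers ellipsoid axis ratios", {
  g <- grid_spec(c(64, 64, 32), 0.5)
  x <- ax(64, 0.5); z <- ax(32, 0.5)
  # 2:1:1 ellipsoid, long axis along y, projected along z
  f <- array(0, dim = c(64, 64, 32))
  for (kz in seq_along(z)) {
    f[, , kz] <- (outer((x - 16)^2 / 16, (x - 16)^2 / 64, `+`) +
                    (z[kz] - 8)^2 / 16 <= 1) * 1
  }
  expect_lt(abs(aspect_ratio_projection(f, g, 3) - 2), 0.05)
  ball <- tanh_sphere(n = 48, h = 0.5, R = 8)
  expect_lt(abs(aspect_ratio_projection(ball, grid_spec(c(48, 48, 48), 0.5),
                                        3) - 1), 0.02)
})

test_that("contact area vanishes far away and tracks the footprint on a slab", {
  g <- grid_spec(c(48, 48, 48), 1)
  sub <- slab_substrate(g, base = 4)
  far <- tanh_sphere(n = 48, h = 1, R = 7, center = c(24, 24, 36))
  expect_lt(contact_area(far, sub, g, G = 4),
            1e-6 * surface_area(far, g))
  # flattened pancake resting at the contact standoff: contact ~ footprint
  x <- ax(48, 1)
  r2d <- sqrt(outer((x - 24)^2, (x - 24)^2, `+`))
  radial <- 0.5 * (1 - tanh((r2d - 12) / 1))
  cap <- array(0, dim = c(48, 48, 48))
  for (kz in seq_along(x)) {
    zprof <- 0.5 * (1 - tanh((x[kz] - 11) / 1)) *
      0.5 * (1 + tanh((x[kz] - 5) / 1))
    cap[, , kz] <- radial * zprof
  }
  foot <- pi * 12^2
  ca <- contact_area(cap, sub, g, G = 4)
  expect_lt(abs(ca - foot) / foot, 0.3)
  # moving a rigid profile closer never decreases contact
  heights <- c(30, 24, 18, 14)
  cas <- vapply(heights, function(zc) {
    contact_area(tanh_sphere(n = 48, h = 1, R = 7, center = c(24, 24, zc)),
                 sub, g, G = 4)
  }, 0)
  expect_true(all(diff(cas) >= -1e-9))
})

test_that("membrane glyphs block-average p and flag the exact top magnitudes", {
  g <- grid_spec(c(32, 32, 32), 1)
  rho <- tanh_sphere(n = 32, h = 1, R = 8)
  p <- array(0, dim = c(32, 32, 32, 3))
  p[, , , 3] <- 0.7
  gl <- p_field_glyphs(p, rho, g, stride = 3, top_n = 10, G = 4)
  expect_true(all(abs(gl$pz - 0.7) < 1e-12))
  expect_true(all(abs(gl$mag - 0.7) < 1e-12))
  # top-n flag equals a full sort on magnitude
  set.seed(4)
  p[, , , 3] <- array(runif(32^3), dim = rep(32, 3))
  gl2 <- p_field_glyphs(p, rho, g, stride = 3, top_n = 25, G = 4)
  expect_setequal(which(gl2$top), order(gl2$mag, decreasing = TRUE)[1:25])
})

test_that("curvature map meshes are closed and match the sphere oracle", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  rho <- tanh_sphere(n = 48, h = 0.5, R = 8)
  mesh <- curvature_map_mesh(rho, 0.5)
  welded <- merge_mesh_vertices(mesh)
  V <- nrow(welded$vertices); Fc <- nrow(welded$triangles)
  expect_equal(V - (3 * Fc / 2) + Fc, 2)          # Euler characteristic
  expect_lt(abs(mean(mesh$curvature) + 2 / 8) / (2 / 8), 0.1)
  expect_lt(stats::sd(mesh$curvature) / abs(mean(mesh$curvature)), 0.2)
  # vertex-area weights integrate to the mesh area
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 2], ] - v[tr[, 1], ]; b <- v[tr[, 3], ] - v[tr[, 1], ]
  areas <- sqrt((a[, 2] * b[, 3] - a[, 3] * b[, 2])^2 +
                (a[, 3] * b[, 1] - a[, 1] * b[, 3])^2 +
                (a[, 1] * b[, 2] - a[, 2] * b[, 1])^2) / 2
  expect_lt(abs(sum(areas) - mesh_area(mesh)) / mesh_area(mesh), 0.01)
})

test_that("implicit Gaussian curvature matches the sphere closed form", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  rho <- tanh_sphere(n = 48, h = 0.5, R = 8)
  K <- implicit_gaussian_curvature(rho, g, grad_min = 0.05)
  sel <- abs(rho - 0.5) < 0.1 & !is.na(K)
  expect_lt(abs(mean(K[sel]) - 1 / 64) / (1 / 64), 0.2)
})
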