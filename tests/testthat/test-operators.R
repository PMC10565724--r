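# discrete operators against analytic oracles

test_that("gradient reproduces analytic derivatives and converges at O(h^2)", {
  g <- grid_spec(c(16, 12, 12), 1)
  f <- field_array(g, fill = 3.7)
  expect_equal(max(abs(fd_gradient(f, g))), 0)

  ramp <- array(rep(ax(16, 1), times = 12 * 12), dim = c(16, 12, 12))
  gr <- fd_gradient(ramp, g)
  expect_equal(gr[5:12, 6, 6, 1], rep(1, 8))
  expect_equal(max(abs(gr[5:12, 6, 6, 2:3])), 0)

  k <- 2 * pi / 16
  err_at <- function(h) {
    n <- round(32 / h)
    gg <- grid_spec(c(n, 12, 12), h)
    x <- ax(n, h)
    f <- array(rep(sin(k * x), times = 12 * 12), dim = c(n, 12, 12))
    gr <- fd_gradient(f, gg)
    interior <- seq(round(n / 4), round(3 * n / 4))
    max(abs(gr[interior, 6, 6, 1] - k * cos(k * x[interior])))
  }
  e1 <- err_at(0.5); e2 <- err_at(0.25)
  expect_lt(e1, k^3 * 0.5^2)       # within the leading truncation bound
  expect_gt(e1 / e2, 3)            # ~4x reduction when h halves
})

test_that("laplacian matches analytic values with zero-flux closure", {
  g <- grid_spec(c(12, 12, 12), 1)
  expect_equal(max(abs(fd_laplacian(field_array(g, 2), g))), 0)

  x <- ax(12, 1)
  quad <- outer(outer(x^2, x^2, `+`), x^2, `+`)
  lp <- fd_laplacian(quad, g)
  expect_equal(lp[4:9, 4:9, 4:9], array(6, dim = c(6, 6, 6)))

  k <- 2 * pi / 16
  err_at <- function(h) {
    n <- round(32 / h)
    gg <- grid_spec(c(n, 12, 12), h)
    x <- ax(n, h)
    f <- array(rep(sin(k * x), times = 144), dim = c(n, 12, 12))
    lp <- fd_laplacian(f, gg)
    interior <- seq(round(n / 4), round(3 * n / 4))
    max(abs(lp[interior, 6, 6] + k^2 * sin(k * x[interior])))
  }
  expect_gt(err_at(0.5) / err_at(0.25), 3)
})

test_that("laplacian conserves mass under explicit diffusion", {
  f <- tanh_sphere(n = 24, h = 1, R = 6)
  out <- phasecell:::cpp_diffuse(f, 1, 0.05, 200, 1)
  expect_lt(abs(sum(out) - sum(f)) / sum(f), 1e-10)
})

test_that("membrane indicator peaks at the interface and narrows with G", {
  expect_equal(membrane_indicator(0.5, G = 14), 1)
  expect_equal(membrane_indicator(0, G = 9), membrane_indicator(1, G = 9))
  expect_equal(membrane_indicator(0, G = 14), 1 - tanh(7)^2)
  # integrated width over rho-space decreases monotonically in G
  rho <- seq(0, 1, by = 1e-4)
  widths <- vapply(c(2, 4, 8, 14, 20),
                   function(G) mean(membrane_indicator(rho, G)), 0)
  expect_true(all(diff(widths) < 0))
  expect_error(membrane_indicator(0.5, G = -1), "positive")
})

test_that("interface curvature matches sphere, cylinder and plane oracles", {
  g <- grid_spec(c(48, 48, 48), 0.5)
  # plane: zero curvature on the midplane
  slab <- tanh_slab(n = 48, h = 0.5)
  cs <- interface_curvature(slab, 0.5)
  mid <- abs(slab - 0.5) < 0.2
  expect_lt(max(abs(cs[mid])), 0.02)
  # spheres: c = -2/R within 15% for R in 6, 8, 12
  for (R in c(6, 8, 12)) {
    f <- tanh_sphere(n = 64, h = 0.5, R = R)
    cc <- interface_curvature(f, 0.5)
    sel <- abs(f - 0.5) < 0.2
    expect_lt(abs(mean(cc[sel]) + 2 / R) / (2 / R), 0.15)
  }
  # cylinder: c = -1/R
  f <- tanh_cylinder(n = 48, h = 0.5, R = 8)
  cc <- interface_curvature(f, 0.5)
  sel <- abs(f - 0.5) < 0.2
  expect_lt(abs(mean(cc[sel]) + 1 / 8) / (1 / 8), 0.15)
  # bulk voxels carry zero curvature
  expect_equal(cc[1, 1, 1], 0)
})

test_that("co-area surface estimator matches slab and sphere areas", {
  g <- grid_spec(c(24, 24, 24), 0.5)
  expect_equal(surface_area(field_array(g), g), 0)
  # half-space interface in an L^3 box integrates to L^2
  L <- 24 * 0.5
  expect_lt(abs(surface_area(tanh_slab(n = 24, h = 0.5), 0.5) - L^2) / L^2,
            0.01)
  f <- tanh_sphere(n = 48, h = 0.5, R = 8)
  expect_lt(abs(surface_area(f, 0.5) - 4 * pi * 64) / (4 * pi * 64), 0.05)
})

test_that("surface area and volume are invariant under voxel translation", {
  # narrow interface so the diffuse tails vanish before the box faces
  f <- tanh_sphere(n = 48, h = 0.5, R = 5, w = 0.7, center = c(11.5, 11.5, 11.5))
  f2 <- tanh_sphere(n = 48, h = 0.5, R = 5, w = 0.7,
                    center = c(11.5, 11.5, 11.5) + 3 * 0.5)
  expect_lt(abs(surface_area(f, 0.5) - surface_area(f2, 0.5)) /
              surface_area(f, 0.5), 1e-6)
  expect_lt(abs(cell_volume(f, 0.5) - cell_volume(f2, 0.5)) /
              cell_volume(f, 0.5), 1e-6)
})

test_that("cell volume is exact for the initial cube and linear in rho", {
  g <- grid_spec(c(32, 32, 32), 1)
  st <- initialize_cell(g, c(16, 16, 16), edge = 17)
  expect_equal(cell_volume(st$rho, g), 17^3)
  expect_equal(cell_volume(0.5 * st$rho, g), 17^3 / 2)
  # the same cube at spacing 0.5 has the same physical volume
  g2 <- grid_spec(c(64, 64, 64), 0.5)
  st2 <- initialize_cell(g2, c(16, 16, 16), edge = 17)
  expect_equal(cell_volume(st2$rho, g2), 17^3)
})
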