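test_that("Helmholtz axial field has the 0.716 center coefficient and even symmetry", {
  a <- 0.075
  hh <- helmholtz_coil(a, 1)
  expect_equal(helmholtz_axial_field(hh, 0) * a / MU0, 0.716,
               tolerance = 0.001 / 0.716)
  # analytic value of the optimal-spacing coefficient
  expect_equal(helmholtz_axial_field(hh, 0) * a / MU0, (4 / 5)^1.5,
               tolerance = 1e-12)
  zs <- c(0.005, 0.013, 0.02)
  expect_equal(helmholtz_axial_field(hh, zs),
               helmholtz_axial_field(hh, -zs))
  expect_equal(helmholtz_axial_field(helmholtz_coil(a, 0), 0.01), 0)
  # linear in ampere-turns
  expect_equal(helmholtz_axial_field(helmholtz_coil(a, 7), zs),
               7 * helmholtz_axial_field(hh, zs))
  expect_error(helmholtz_axial_field(maxwell_coil(a, 1), 0),
               "role 'helmholtz'")
})

test_that("Helmholtz axial field agrees with Biot-Savart quadrature off center", {
  a <- 0.075
  hh <- helmholtz_coil(a, 1)
  z <- 0.01
  expect_equal(helmholtz_axial_field(hh, z), bs_pair_Bz(hh, z),
               tolerance = 1e-6)
})

test_that("Maxwell axial gradient: 0.641 coefficient, symmetry, flatness, quadrature", {
  a <- 0.075
  mx <- maxwell_coil(a, 1)
  expect_equal(maxwell_axial_gradient(mx, 0) * a^2 / MU0, 0.641,
               tolerance = 0.001 / 0.641)
  expect_equal(maxwell_axial_gradient(mx, 0) * a^2 / MU0,
               (3 * sqrt(3) / 2) / (7 / 4)^2.5, tolerance = 1e-12)
  zs <- c(0.004, 0.011, 0.02)
  expect_equal(maxwell_axial_gradient(mx, zs),
               maxwell_axial_gradient(mx, -zs))
  expect_equal(maxwell_axial_gradient(maxwell_coil(a, 0), 0.01), 0)
  expect_error(maxwell_axial_gradient(helmholtz_coil(a, 1), 0),
               "role 'maxwell'")
  # finite difference of the quadrature-computed field
  z <- 0.02
  hstep <- 1e-5
  fd <- (bs_pair_Bz(mx, z + hstep) - bs_pair_Bz(mx, z - hstep)) /
    (2 * hstep)
  expect_equal(maxwell_axial_gradient(mx, z), fd, tolerance = 1e-5)
  # maximally flat at optimal spacing: center curvature vanishes there and
  # is distinctly nonzero at perturbed spacings
  curv <- function(d) {
    m <- maxwell_coil(a, 1, spacing_d = d)
    dz <- 1e-3
    (maxwell_axial_gradient(m, dz) - 2 * maxwell_axial_gradient(m, 0) +
        maxwell_axial_gradient(m, -dz)) / dz^2
  }
  c_opt <- abs(curv(sqrt(3) * a))
  expect_lt(c_opt, abs(curv(1.6 * a)) / 100)
  expect_lt(c_opt, abs(curv(1.9 * a)) / 100)
})

test_that("loop_field: on-axis limit, mirror symmetry, wire singularity, solenoidality", {
  a <- 0.06
  z0 <- 0.01
  nI <- 3
  # on-axis closed form
  for (z in c(-0.03, 0, 0.04)) {
    B <- loop_field(a, z0, nI, c(0, 0, z))
    expect_equal(unname(B[1:2]), c(0, 0))
    expect_equal(unname(B[3]),
                 MU0 * nI * a^2 / (2 * (a^2 + (z - z0)^2)^1.5))
  }
  # mirror-symmetric points: equal axial, opposite radial components
  Bp <- loop_field(a, z0, nI, c(0, 0.02, 0.03))
  Bm <- loop_field(a, z0, nI, c(0, -0.02, 0.03))
  expect_equal(unname(Bp[3]), unname(Bm[3]))
  expect_equal(unname(Bp[2]), -unname(Bm[2]))
  expect_error(loop_field(a, z0, nI, c(a, 0, z0)), "singular")
  # div B = 0 by central differences at random interior points
  set.seed(42)
  hstep <- 1e-6
  for (i in 1:5) {
    p <- runif(3, -0.02, 0.02)
    div <- 0
    for (ax in 1:3) {
      dp <- c(0, 0, 0)
      dp[ax] <- hstep
      div <- div + (loop_field(a, z0, nI, p + dp)[ax] -
                      loop_field(a, z0, nI, p - dp)[ax]) / (2 * hstep)
    }
    Bmag <- sqrt(sum(loop_field(a, z0, nI, p)^2))
    expect_lt(abs(div) * 0.02 / Bmag, 1e-4)
  }
})

test_that("loop_field matches brute-force Biot-Savart at off-axis points", {
  a <- 0.075
  z0 <- -0.02
  nI <- 2.5
  set.seed(7)
  for (i in 1:5) {
    p <- runif(3, -0.025, 0.025)
    expect_equal(unname(loop_field(a, z0, nI, p)),
                 bs_loop_field(a, z0, nI, p), tolerance = 1e-6)
  }
})

test_that("pair_field superposes the four loops and reduces to the closed forms on axis", {
  a <- 0.075
  hh <- helmholtz_coil(a, 1e4)
  mx <- maxwell_coil(a, 1e3)
  s0 <- pair_field(hh, mx, c(0, 0, 0))
  expect_equal(s0$B[3], helmholtz_axial_field(hh, 0), tolerance = 1e-9)
  expect_equal(s0$B[1:2], c(0, 0))
  expect_equal(s0$dBz_dz, maxwell_axial_gradient(mx, 0), tolerance = 1e-6)
  # z-axis sweep: Bz is the Helmholtz closed form (Maxwell loops cancel
  # nothing off center, they add their own antisymmetric part)
  for (z in c(-0.02, 0.015)) {
    s <- pair_field(hh, mx, c(0, 0, z))
    mx_bz <- MU0 * mx$ampere_turns * a^2 / 2 *
      (((z - mx$spacing_d / 2)^2 + a^2)^-1.5 -
         ((z + mx$spacing_d / 2)^2 + a^2)^-1.5)
    expect_equal(s$B[3], helmholtz_axial_field(hh, z) + mx_bz,
                 tolerance = 1e-9)
  }
  # antisymmetry: a Maxwell pair alone has zero Bz at the center plane
  s_m <- pair_field(helmholtz_coil(a, 0), mx, c(0.01, -0.005, 0))
  expect_equal(s_m$B[3], 0, tolerance = 1e-12)
})

test_that("force vectors over the imaging plane point dominantly along +z at 10:1 currents", {
  a <- 0.075
  hh <- helmholtz_coil(a, 1e4)
  mx <- maxwell_coil(a, 1e3)
  xs <- seq(-a / 3, a / 3, length.out = 11)
  grid <- as.matrix(expand.grid(x = 0, y = xs, z = xs))
  Fv <- force_vector_field(hh, mx, nanoparticle_load(weight_w = 1e-3),
                           grid)
  # frozen regression of the vector-map character (implementation-derived)
  expect_equal(mean(Fv[, 3] > 0), 0.8926, tolerance = 1e-3)
  expect_gt(mean(Fv[, 3] > 0 & abs(Fv[, 3]) >= abs(Fv[, 2])), 0.7)
})

test_that("force_on_load: saturated coefficient 12.8, regimes and zero cases", {
  a <- 0.075
  mx <- maxwell_coil(a, 1e3)
  w <- 2e-3
  load <- nanoparticle_load(saturation_magnetization = 20, weight_w = w)
  sample <- field_sample(c(0, 0, 0), c(0, 0, 0.4),
                         maxwell_axial_gradient(mx, 0))
  Fz <- force_on_load(load, sample)[3]  # auto: |B| = 0.4 T is saturated
  coeff <- Fz * a^2 / (w * MU0 * mx$ampere_turns)
  expect_equal(coeff, 12.8, tolerance = 0.005)
  expect_equal(force_on_load(nanoparticle_load(weight_w = 0), sample),
               c(0, 0, 0))
  # below saturation the moment follows chi * H, capped at saturation
  chi_load <- nanoparticle_load(saturation_magnetization = 20,
                                susceptibility_chi = 1e-4, weight_w = w)
  s_low <- field_sample(c(0, 0, 0), c(0, 0, 0.1), 1)
  expect_equal(force_on_load(chi_load, s_low)[3],
               1e-4 * 0.1 / MU0 * w * 1)
  # moment times finite-difference gradient reproduces the axial force
  hz <- 1e-4
  sA <- pair_field(helmholtz_coil(a, 1e4), mx, c(0, 0, -hz))
  sB <- pair_field(helmholtz_coil(a, 1e4), mx, c(0, 0, hz))
  fd_grad <- (sB$B[3] - sA$B[3]) / (2 * hz)
  s0 <- pair_field(helmholtz_coil(a, 1e4), mx, c(0, 0, 0))
  expect_equal(force_on_load(load, s0, regime = "saturated")[3],
               20 * w * fd_grad, tolerance = 1e-4)
  # auto regime: the 0.12 T center field of this pair is below the 0.4 T
  # saturation threshold, and a chi = 0 load then carries no moment
  expect_equal(force_on_load(load, s0)[3], 0)
})

test_that("required ampere-turns invert the center formulas", {
  a <- 0.075
  nI <- required_helmholtz_ampere_turns(0.4, a)
  expect_equal(nI, 3.34e4, tolerance = 0.005)
  expect_equal(required_helmholtz_ampere_turns(0, a), 0)
  # round trip
  expect_equal(helmholtz_axial_field(helmholtz_coil(a, nI), 0), 0.4,
               tolerance = 0.002)
  load <- nanoparticle_load(saturation_magnetization = 20,
                            weight_w = 1e-3)
  nI2 <- required_maxwell_ampere_turns(0.02, load, a)
  expect_equal(required_maxwell_ampere_turns(0, load, a), 0)
  mx <- maxwell_coil(a, nI2)
  s <- field_sample(c(0, 0, 0), c(0, 0, 0.4),
                    maxwell_axial_gradient(mx, 0))
  expect_equal(force_on_load(load, s, regime = "saturated")[3], 0.02,
               tolerance = 0.002)
  expect_error(required_maxwell_ampere_turns(
    0.01, nanoparticle_load(weight_w = 0), a), "weight")
  # current-force curve is linear and increasing over 10-40 mN
  F_sweep <- seq(0.01, 0.04, length.out = 7)
  nIs <- vapply(F_sweep, required_maxwell_ampere_turns, numeric(1),
                load = nanoparticle_load(20, weight_w = 1e-3),
                radius_a = a)
  expect_true(all(diff(nIs) > 0))
  expect_equal(nIs / F_sweep, rep(nIs[1] / F_sweep[1], 7))
})

test_that("imaging-volume uniformity report: symmetry and frozen regression values", {
  hh <- helmholtz_coil(0.075, 1e4)
  mx <- maxwell_coil(0.075, 1e3)
  u <- imaging_volume_uniformity(hh, mx, grid_n = 9L)
  expect_equal(u$side_m, 2 * 0.075 / 3)
  prof <- u$axial_profile
  # the Maxwell gradient is even in z; the full pair profile is not, since
  # the Helmholtz pair contributes an odd field gradient off center
  expect_equal(prof$dBz_dz_maxwell_only, rev(prof$dBz_dz_maxwell_only),
               tolerance = 1e-12)
  expect_equal(prof$relative_deviation[(nrow(prof) + 1) / 2], 0,
               tolerance = 1e-9)
  # frozen regression values (implementation-derived, not paper values):
  # the full pair force is strongly non-uniform off center because the
  # Helmholtz pair's own field gradient enters at 10:1 excitation, while
  # the Maxwell gradient alone is flat to ~3% over the cube
  expect_equal(max(prof$relative_deviation), 1.6057, tolerance = 1e-3)
  expect_equal(u$max_relative_deviation, 4.1214, tolerance = 1e-3)
  expect_equal(u$max_axial_deviation_gradient_only, 0.030602,
               tolerance = 1e-4)
})

test_that("coil_spec and nanoparticle_load validate their inputs", {
  expect_error(coil_spec(-1, 10), "radius")
  expect_error(coil_spec(0.075, Inf), "finite")
  expect_error(coil_spec(0.075, 10, spacing_d = 0), "spacing")
  expect_equal(helmholtz_coil(0.08, 5)$spacing_d, 0.08)
  expect_equal(maxwell_coil(0.08, 5)$spacing_d, sqrt(3) * 0.08)
  expect_error(nanoparticle_load(-1), ">= 0")
})
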