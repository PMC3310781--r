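test_that("Laplacian force map is exact on quadratics and zero on zero fields", {
  n <- 31L
  h <- c(1e-3, 1e-3)
  ys <- seq(0, by = h[1], length.out = n)
  zs <- seq(0, by = h[2], length.out = n)
  cc <- 5
  uz <- outer(ys^2, zs^0) + outer(ys^0, zs^2)  # y^2 + z^2
  fld <- make_field_2d(matrix(0, n, n), cc * uz, h)
  G <- 3000
  m <- laplacian_force_map(fld, G)
  inner <- m$Fz[2:(n - 1), 2:(n - 1)]
  expect_equal(inner, matrix(-4 * cc * G, n - 2L, n - 2L),
               tolerance = 1e-9)
  # boundary ring is flagged invalid, not extrapolated
  expect_true(all(is.na(m$Fz[1, ])) && all(is.na(m$Fz[, n])))
  f0 <- make_field_2d(matrix(0, n, n), matrix(0, n, n), h)
  expect_true(all(laplacian_force_map(f0, G)$Fz[2:(n - 1), 2:(n - 1)] == 0))
  tiny <- make_field_2d(matrix(0, 2, 2), matrix(0, 2, 2), h)
  expect_error(laplacian_force_map(tiny, G), "grid too small")
})

test_that("full inversion recovers the applied force of the forward solution", {
  pl <- single_inclusion_pipeline()
  mf <- full_force_map(pl$field, pl$G, pl$nu)
  mask <- pl$phantom$inclusion_mask
  interior <- as.numeric(mean_intensity_in_mask(mf, mask))
  expect_equal(interior, pl$force_density, tolerance = 0.05)
  bg <- !mask & is.finite(mf$Fz)
  expect_lt(abs(mean(mf$Fz[bg])) / pl$force_density, 0.02)
  # constant displacement (zero Laplacian, zero divergence) -> zero map
  n <- 21L
  h <- c(1e-3, 1e-3)
  fc <- make_field_2d(matrix(2e-6, n, n), matrix(-1e-6, n, n), h)
  mz <- full_force_map(fc, pl$G, pl$nu)
  expect_equal(max(abs(mz$Fz), na.rm = TRUE), 0)
  expect_error(full_force_map(pl$field, pl$G, 0.5), "singular")
})

test_that("Laplacian-only map shows the incompressible-limit interior bias and boundary overshoot", {
  pl <- single_inclusion_pipeline()
  ml <- laplacian_force_map(pl$field, pl$G)
  mask <- pl$phantom$inclusion_mask
  interior <- as.numeric(mean_intensity_in_mask(ml, mask))
  # dropping the divergence term costs the depolarization factor of the
  # disc: the interior plateau sits at f * (1 - 1/(2(2 - 2 nu))) ~ 0.505 f
  # at nu = 0.495, not at f
  factor_expected <- 1 - 1 / (2 * (2 - 2 * pl$nu))
  expect_equal(interior / pl$force_density, factor_expected,
               tolerance = 0.03)
  # boundary overshoot: the shell max exceeds the interior plateau
  expect_gt(halo_metric(ml, mask), 1)
})

test_that("divergence term suppresses the halo on single- and double-inclusion phantoms", {
  for (pl in list(single_inclusion_pipeline(), double_inclusion_pipeline())) {
    mf <- full_force_map(pl$field, pl$G, pl$nu)
    ml <- laplacian_force_map(pl$field, pl$G)
    for (mask in phantom_masks(pl$phantom)) {
      expect_lt(halo_metric(mf, mask), halo_metric(ml, mask))
    }
  }
})

test_that("normalization: unit peak, idempotence, sign preservation, zero-map error", {
  pl <- single_inclusion_pipeline()
  m <- laplacian_force_map(pl$field, pl$G)
  nm <- normalize_map(m)
  expect_equal(max(abs(nm$Fz[is.finite(nm$Fz)])), 1)
  expect_equal(normalize_map(nm)$Fz, nm$Fz)
  expect_equal(sign(nm$Fz), sign(m$Fz))
  z <- m
  z$Fz[] <- 0
  expect_error(normalize_map(z), "all-zero")
})

test_that("mean intensity in mask: uniform maps, erosion control and errors", {
  n <- 21L
  h <- c(1e-3, 1e-3)
  fld <- make_field_2d(matrix(0, n, n), matrix(0, n, n), h)
  m <- mnpmap:::new_force_map(matrix(7.5, n, n), "laplacian_only", fld)
  mask <- matrix(FALSE, n, n)
  mask[8:14, 8:14] <- TRUE
  expect_equal(as.numeric(mean_intensity_in_mask(m, mask)), 7.5)
  one <- matrix(FALSE, n, n)
  one[11, 11] <- TRUE
  m$Fz[11, 11] <- -3
  expect_equal(as.numeric(mean_intensity_in_mask(m, one, erode = FALSE)),
               -3)
  expect_error(mean_intensity_in_mask(m, matrix(FALSE, n, n)), "empty")
})

test_that("linearity report: exact proportionality, permutation invariance, errors", {
  x <- c(100, 200, 300, 400, 500)
  y <- 0.51 * x
  fit <- linearity_report(x, y)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$slope, 0.51)
  p <- c(3, 1, 5, 2, 4)
  fit_p <- linearity_report(x[p], y[p])
  expect_equal(fit_p$slope, fit$slope)
  expect_equal(fit_p$r_squared, fit$r_squared)
  expect_error(linearity_report(c(1, 2), c(1, 2)), "at least 3")
})

test_that("pipeline mean intensity is linear in the applied force", {
  pl <- single_inclusion_pipeline(grid_n = 101L)
  ph <- pl$phantom
  levels <- c(500, 1000, 1500, 2000, 2500)
  means <- vapply(levels, function(f) {
    phi <- ph
    phi$force_density_Fz[phi$inclusion_mask] <- f
    as.numeric(mean_intensity_in_mask(
      laplacian_force_map(solve_static(phi), pl$G), ph$inclusion_mask))
  }, numeric(1))
  fit <- linearity_report(levels, means)
  expect_gte(fit$r_squared, 0.999)
  expect_lt(fit$relative_intercept, 0.01)
})

test_that("halo metric: zero for perfect recovery, scale invariant, errors", {
  n <- 41L
  h <- c(1e-3, 1e-3)
  ys <- seq(-0.02, 0.02, length.out = n)
  mask <- outer(ys^2, ys^2, `+`) < 0.006^2
  fld <- make_field_2d(matrix(0, n, n), matrix(0, n, n), h,
                       extent_m = c(0.04, 0.04))
  perfect <- mnpmap:::new_force_map(ifelse(mask, 1200, 0),
                                    "full_navier", fld)
  expect_equal(halo_metric(perfect, mask), 0)
  pl <- single_inclusion_pipeline()
  m <- laplacian_force_map(pl$field, pl$G)
  mask2 <- pl$phantom$inclusion_mask
  expect_equal(halo_metric(normalize_map(m), mask2),
               halo_metric(m, mask2), tolerance = 1e-12)
  expect_error(halo_metric(perfect, matrix(FALSE, n, n)), "empty")
})

test_that("density conversion inverts the force model", {
  pl <- single_inclusion_pipeline()
  m <- full_force_map(pl$field, pl$G, pl$nu)
  d1 <- density_from_force(m, gradient = 0.2)
  d2 <- density_from_force(m, gradient = 0.4)
  expect_equal(d2$magnetization_Mz, d1$magnetization_Mz / 2)
  expect_error(density_from_force(m, gradient = 0), "nonzero")
  z <- m
  z$Fz[] <- 0
  expect_true(all(density_from_force(z, 0.2)$magnetization_Mz == 0))
  # round trip against the pointwise force model: a voxel of volume V with
  # mass density rho_w has weight rho_w * V and force
  # Msat * rho_w * V * dBz/dz, i.e. force density Msat * rho_w * dBz/dz
  Msat <- 20
  rho_w <- 0.05  # kg/m^3
  grad <- 0.143
  load <- nanoparticle_load(Msat, weight_w = rho_w * 1)  # unit volume
  Fz <- force_on_load(load, field_sample(c(0, 0, 0), c(0, 0, 0.4), grad),
                      regime = "saturated")[3]
  mm <- m
  mm$Fz[] <- Fz
  back <- density_from_force(mm, grad, specific_moment = Msat)
  expect_equal(back$mass_density[1, 1], rho_w, tolerance = 1e-12)
})
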