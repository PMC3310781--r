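# Independent oracles and shared fixtures.
#
# The magnetostatic oracle integrates the Biot-Savart law directly by
# midpoint quadrature over the wire; the elasticity oracle integrates the
# Kelvin point-force kernel over the loaded ball on a Cartesian grid.
# Both are deliberately brute-force and independent of the package's
# closed-form / FEM code paths.

# field of one circular loop by Biot-Savart midpoint quadrature
bs_loop_field <- function(loop_radius, loop_z, ampere_turns, point,
                          nseg = 1e4L) {
  phi <- (seq_len(nseg) - 0.5) * 2 * pi / nseg
  dphi <- 2 * pi / nseg
  src <- cbind(loop_radius * cos(phi), loop_radius * sin(phi), loop_z)
  dl <- cbind(-loop_radius * sin(phi), loop_radius * cos(phi), 0) * dphi
  r <- cbind(point[1] - src[, 1], point[2] - src[, 2], point[3] - src[, 3])
  rn <- sqrt(rowSums(r^2))
  cross <- cbind(dl[, 2] * r[, 3] - dl[, 3] * r[, 2],
                 dl[, 3] * r[, 1] - dl[, 1] * r[, 3],
                 dl[, 1] * r[, 2] - dl[, 2] * r[, 1])
  MU0 * ampere_turns / (4 * pi) * colSums(cross / rn^3)
}

# axial field of a coil pair by quadrature (role fixes the current signs)
bs_pair_Bz <- function(coil, z, nseg = 1e4L) {
  s_bot <- if (coil$role == "maxwell") -1 else 1
  vapply(z, function(zz) {
    bs_loop_field(coil$radius_a, coil$spacing_d / 2, coil$ampere_turns,
                  c(0, 0, zz), nseg)[3] +
      bs_loop_field(coil$radius_a, -coil$spacing_d / 2,
                    s_bot * coil$ampere_turns, c(0, 0, zz), nseg)[3]
  }, numeric(1))
}

# Kelvin point-force displacement (force Fz at src, evaluation at x)
kelvin_point_u <- function(x, src, Fz, G, nu) {
  dx <- x - src
  r <- sqrt(sum(dx^2))
  C <- Fz / (16 * pi * G * (1 - nu))
  u <- C * dx * dx[3] / r^3
  u[3] <- u[3] + C * (3 - 4 * nu) / r
  u
}

# displacement of a uniformly loaded ball by grid quadrature of the
# Kelvin kernel
kelvin_ball_numeric <- function(x, f, R, G, nu, n = 31L) {
  g <- seq(-R, R, length.out = n)
  hv <- (g[2] - g[1])^3
  u <- c(0, 0, 0)
  for (sx in g) for (sy in g) for (sz in g) {
    if (sx^2 + sy^2 + sz^2 < R^2) {
      src <- c(sx, sy, sz)
      if (sum((x - src)^2) > 1e-12)
        u <- u + kelvin_point_u(x, src, f * hv, G, nu)
    }
  }
  u
}

# hand-built displacement field on a regular 2D grid (for stencil tests)
make_field_2d <- function(uy, uz, h, extent_m = h * (dim(uz) - 1L)) {
  structure(list(u = list(uy = uy, uz = uz), voxel_size_h = h,
                 grid_shape = dim(uz), dim = 2L, extent_m = extent_m,
                 boundary_condition_tag = "synthetic",
                 solver_info = list(method = "synthetic")),
            class = "displacement_field")
}

# cached standard pipelines (solves are the expensive part of the suite)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

single_inclusion_pipeline <- function(grid_n = 201L, force_density = 2000) {
  cached(paste0("single_inc_", grid_n, "_", force_density), {
    ph <- build_phantom_2d(inclusions = list(list(
      center = c(0, 0), diameter = 0.01, force_density = force_density)),
      grid_n = grid_n)
    fld <- solve_static(ph)
    list(phantom = ph, field = fld, G = ph$medium$G, nu = ph$medium$nu,
         force_density = force_density)
  })
}

double_inclusion_pipeline <- function(grid_n = 201L, force_density = 2000) {
  cached(paste0("double_inc_", grid_n, "_", force_density), {
    ph <- build_phantom_2d(inclusions = list(
      list(center = c(-0.0125, 0), diameter = 0.01,
           force_density = force_density),
      list(center = c(0.0125, 0), diameter = 0.005,
           force_density = force_density)),
      grid_n = grid_n)
    fld <- solve_static(ph)
    list(phantom = ph, field = fld, G = ph$medium$G, nu = ph$medium$nu,
         force_density = force_density)
  })
}

# per-inclusion circular masks for a 2D phantom
phantom_masks <- function(ph) {
  ys <- seq(-ph$extent_m[1] / 2, ph$extent_m[1] / 2,
            length.out = ph$grid_shape[1])
  zs <- seq(-ph$extent_m[2] / 2, ph$extent_m[2] / 2,
            length.out = ph$grid_shape[2])
  lapply(ph$inclusions, function(inc) {
    d2 <- outer((ys - inc$center[1])^2, (zs - inc$center[2])^2, `+`)
    d2 < (inc$diameter / 2)^2
  })
}
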