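#' Linear isotropic elastic medium
#'
#' Material description of the tissue-mimicking phantom. Soft tissues (the
#' normal-breast range this package targets) have Young's modulus 5--30 kPa,
#' Poisson ratio close to the incompressible limit (0.495 here), and density
#' around 1000 kg/m^3. The shear modulus is derived, `G = E / (2 (1 + nu))`,
#' and the density is carried for completeness only — the solver is static.
#'
#' @param youngs_modulus_E Young's modulus (Pa, > 0).
#' @param poisson_nu Poisson ratio, strictly inside (0, 0.5): the
#'   divergence-term factor 1/(1 - 2 nu) is singular at 0.5.
#' @param density_rho Mass density (kg/m^3, > 0).
#' @return An object of class `elastic_medium` with fields `E`, `nu`, `rho`,
#'   `G`.
#' @export
elastic_medium <- function(youngs_modulus_E = 10e3, poisson_nu = 0.495,
                           density_rho = 1000) {
  stopifnot(is.numeric(youngs_modulus_E), youngs_modulus_E > 0,
            is.numeric(poisson_nu), is.numeric(density_rho), density_rho > 0)
  if (poisson_nu <= 0 || poisson_nu >= 0.5)
    stop("poisson_nu must lie strictly in (0, 0.5); ",
         "nu = 0.5 makes the 1/(1 - 2 nu) divergence factor singular")
  structure(list(E = youngs_modulus_E, nu = poisson_nu, rho = density_rho,
                 G = youngs_modulus_E / (2 * (1 + poisson_nu))),
            class = "elastic_medium")
}

new_phantom <- function(grid_shape, voxel_size_h, medium, mask, force,
                        dim, extent_m, inclusions) {
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_h = voxel_size_h, medium = medium,
                 inclusion_mask = mask, force_density_Fz = force,
                 dim = dim, extent_m = extent_m, inclusions = inclusions),
            class = "phantom")
}

# node-center coordinates along one axis: extent L sampled by n nodes,
# h = L/(n-1), centered on 0
axis_coords <- function(L, n) seq(-L / 2, L / 2, length.out = n)

#' Build a 2D phantom with cylindrical (circular) inclusions
#'
#' A square elastic slab of side `side_cm` on a regular `grid_n x grid_n`
#' grid, with one or more circular inclusions mimicking regions of uniform
#' magnetic-particle density. A uniform axial (+z) body-force density is
#' applied at every grid node whose center lies inside an inclusion and zero
#' force elsewhere. Coordinates are (y lateral, z axial), both centered on
#' the domain center.
#'
#' @param side_cm Domain side (cm). Default 10.
#' @param inclusions List of inclusions, each a list with `center` (length-2
#'   numeric, metres, (y, z) relative to the domain center), `diameter`
#'   (m) and `force_density` (N/m^3). A single inclusion may be passed
#'   unwrapped.
#' @param E Young's modulus (Pa). Default 10 kPa.
#' @param nu Poisson ratio. Default 0.495.
#' @param grid_n Nodes per axis (>= 50, so a 10 mm inclusion spans >= 5
#'   nodes). Default 201 (h = 0.5 mm on a 10 cm domain).
#' @return An object of class `phantom` (`dim = 2`); arrays are indexed
#'   `[iy, iz]`.
#' @examples
#' ph <- build_phantom_2d(inclusions = list(
#'   list(center = c(0, 0), diameter = 0.01, force_density = 100)))
#' sum(ph$inclusion_mask) * prod(ph$voxel_size_h)  # ~ pi * 0.005^2
#' @export
build_phantom_2d <- function(side_cm = 10, inclusions,
                             E = 10e3, nu = 0.495, grid_n = 201L) {
  stopifnot(side_cm > 0, grid_n >= 50L)
  if (!is.null(inclusions$center)) inclusions <- list(inclusions)
  L <- side_cm / 100
  ys <- axis_coords(L, grid_n)
  zs <- axis_coords(L, grid_n)
  h <- L / (grid_n - 1)
  mask <- matrix(FALSE, grid_n, grid_n)
  force <- matrix(0, grid_n, grid_n)
  for (inc in inclusions) {
    stopifnot(length(inc$center) == 2L, inc$diameter > 0)
    r <- inc$diameter / 2
    if (any(abs(inc$center) + r >= L / 2))
      stop("inclusion touches or crosses the domain boundary")
    d2 <- outer((ys - inc$center[1])^2, (zs - inc$center[2])^2, `+`)
    m <- d2 < r^2
    mask <- mask | m
    force[m] <- inc$force_density
  }
  new_phantom(c(grid_n, grid_n), c(h, h), elastic_medium(E, nu),
              mask, force, 2L, c(L, L), inclusions)
}

#' Build a 3D phantom with a spherical inclusion
#'
#' A rectangular elastic block, by default 10 cm x 10 cm x 6 cm, with a
#' single spherical inclusion of diameter `inclusion_D_mm` at the domain
#' center, loaded with a uniform axial body-force density inside the sphere.
#' Coordinates are (x, y, z) with z axial (the 6 cm direction).
#'
#' @param size_cm Length-3 domain extents (cm). Default `c(10, 10, 6)`.
#' @param inclusion_D_mm Sphere diameter (mm), in 5--40; must leave
#'   clearance to every face.
#' @param force_density Uniform force density inside the sphere (N/m^3).
#' @param E Young's modulus (Pa). Default 10 kPa.
#' @param nu Poisson ratio. Default 0.495.
#' @param grid_n Length-3 node counts. Default `c(51, 51, 31)` (h = 2 mm).
#' @return An object of class `phantom` (`dim = 3`); arrays are indexed
#'   `[ix, iy, iz]`.
#' @export
build_phantom_3d <- function(size_cm = c(10, 10, 6), inclusion_D_mm = 10,
                             force_density = 100, E = 10e3, nu = 0.495,
                             grid_n = c(51L, 51L, 31L)) {
  stopifnot(length(size_cm) == 3L, all(size_cm > 0), length(grid_n) == 3L,
            all(grid_n >= 9L))
  if (inclusion_D_mm < 5 || inclusion_D_mm > 40)
    stop("inclusion_D_mm must be in [5, 40] mm")
  L <- size_cm / 100
  r <- inclusion_D_mm / 2000
  if (any(r >= L / 2))
    stop("inclusion does not fit inside the domain with clearance")
  xs <- axis_coords(L[1], grid_n[1])
  ys <- axis_coords(L[2], grid_n[2])
  zs <- axis_coords(L[3], grid_n[3])
  h <- L / (grid_n - 1)
  d2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  mask <- array(d2 < r^2, dim = grid_n)
  force <- array(0, dim = grid_n)
  force[mask] <- force_density
  new_phantom(grid_n, h, elastic_medium(E, nu), mask, force, 3L, L,
              list(list(center = c(0, 0, 0), diameter = 2 * r,
                        force_density = force_density)))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom: %dD>\n", x$dim))
  cat(sprintf("  grid      : %s nodes, h = %s mm\n",
              paste(x$grid_shape, collapse = " x "),
              paste(signif(1000 * x$voxel_size_h, 3), collapse = " x ")))
  cat(sprintf("  extent    : %s cm\n",
              paste(signif(100 * x$extent_m, 3), collapse = " x ")))
  cat(sprintf("  medium    : E = %g kPa, nu = %g, G = %g kPa\n",
              x$medium$E / 1000, x$medium$nu, signif(x$medium$G / 1000, 4)))
  cat(sprintf("  inclusions: %d (%d loaded nodes)\n",
              length(x$inclusions), sum(x$inclusion_mask)))
  invisible(x)
}

#' Add axial measurement noise to a displacement field
#'
#' Emulates the finite precision of elastographic displacement tracking by
#' adding zero-mean Gaussian noise of standard deviation `axial_precision`
#' to the axial (z) displacement component only; lateral components are
#' untouched. Reproducible under a fixed seed.
#'
#' @param field A `displacement_field` from [solve_static()].
#' @param axial_precision Noise standard deviation (m, >= 0).
#' @param seed Integer RNG seed.
#' @return A `displacement_field` with noisy axial component.
#' @export
add_measurement_noise <- function(field, axial_precision, seed = 1L) {
  stopifnot(inherits(field, "displacement_field"), axial_precision >= 0)
  if (axial_precision == 0) return(field)
  uz <- field$u$uz
  set.seed(as.integer(seed))
  noise <- array(rnorm(length(uz), sd = axial_precision), dim = dim(uz))
  field$u$uz <- uz + noise
  field$noise_sd <- axial_precision
  field
}
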