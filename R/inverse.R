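# --- finite-difference helpers ------------------------------------------
# All derivatives are 3-point central stencils; boundary planes get NA
# rather than one-sided differences (one-sided second derivatives amplify
# noise, and the maps of interest are interior-focused).

shift_arr <- function(A, axis, by) {
  d <- dim(A)
  idx <- lapply(d, seq_len)
  src <- idx
  src[[axis]] <- idx[[axis]] + by
  out <- array(NA_real_, dim = d)
  keep <- src[[axis]] >= 1L & src[[axis]] <= d[axis]
  dst <- idx
  dst[[axis]] <- idx[[axis]][keep]
  src[[axis]] <- src[[axis]][keep]
  out <- do.call(`[<-`, c(list(out), dst,
                          list(value = do.call(`[`, c(list(A), src)))))
  out
}

d1_central <- function(A, axis, h) {
  (shift_arr(A, axis, 1L) - shift_arr(A, axis, -1L)) / (2 * h)
}

d2_central <- function(A, axis, h) {
  (shift_arr(A, axis, 1L) - 2 * A + shift_arr(A, axis, -1L)) / h^2
}

# forward difference along `axis` (n-1 entries), then midpoint-average along
# every other axis: the derivative of component `axis` at element centers
elem_center_deriv <- function(A, axis, h) {
  d <- length(dim(A))
  n <- dim(A)
  idx <- lapply(n, seq_len)
  lo <- idx
  hi <- idx
  lo[[axis]] <- seq_len(n[axis] - 1L)
  hi[[axis]] <- lo[[axis]] + 1L
  out <- (do.call(`[`, c(list(A), hi, list(drop = FALSE))) -
            do.call(`[`, c(list(A), lo, list(drop = FALSE)))) / h
  for (ax in setdiff(seq_len(d), axis)) {
    m <- dim(out)
    lo <- lapply(dim(out), seq_len)
    hi <- lo
    lo[[ax]] <- seq_len(m[ax] - 1L)
    hi[[ax]] <- lo[[ax]] + 1L
    out <- (do.call(`[`, c(list(out), hi, list(drop = FALSE))) +
              do.call(`[`, c(list(out), lo, list(drop = FALSE)))) / 2
  }
  out
}

# average an element-centered field onto the nodes (each node receives the
# mean of its up-to-2^d adjacent elements) — the standard checkerboard
# filter for element-constant pressure
elements_to_nodes <- function(E, grid_shape) {
  d <- length(grid_shape)
  acc <- array(0, dim = grid_shape)
  cnt <- array(0, dim = grid_shape)
  ne <- dim(E)
  offs <- do.call(expand.grid, rep(list(0:1), d))
  for (r in seq_len(nrow(offs))) {
    dst <- lapply(seq_len(d), function(k) seq_len(ne[k]) + offs[r, k])
    acc <- do.call(`[<-`, c(list(acc), dst, list(
      value = do.call(`[`, c(list(acc), dst, list(drop = FALSE))) + E)))
    cnt <- do.call(`[<-`, c(list(cnt), dst, list(
      value = do.call(`[`, c(list(cnt), dst, list(drop = FALSE))) + 1)))
  }
  acc / cnt
}

new_force_map <- function(Fz, method, field, normalization = "raw") {
  structure(list(Fz = Fz, method = method, normalization = normalization,
                 voxel_size_h = field$voxel_size_h, dim = field$dim,
                 grid_shape = field$grid_shape, extent_m = field$extent_m),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("<force_map: %s, %s>\n", x$method, x$normalization))
  v <- x$Fz[is.finite(x$Fz)]
  cat(sprintf("  grid : %s\n", paste(x$grid_shape, collapse = " x ")))
  cat(sprintf("  range: [%.4g, %.4g] over %d valid voxels\n",
              min(v), max(v), length(v)))
  invisible(x)
}

#' Force map from the axial Laplacian approximation
#'
#' Recovers the axial force density from the axial displacement alone,
#' \deqn{F_z = -G\left(\frac{\partial^2 u_z}{\partial y^2} +
#'   \frac{\partial^2 u_z}{\partial z^2}\right),}
#' the approximation available when only axial (ultrasound-elastography)
#' displacement is measurable. The elevational (x) second derivative and
#' the divergence term are omitted; the omission produces the
#' characteristic halo overshoot around inclusion boundaries (see
#' [halo_metric()]). Derivatives are 3-point central differences in y and z
#' only; the boundary ring is NA.
#'
#' @param field A `displacement_field` (2D or 3D; 3D uses the y and z axes
#'   of the axial component only).
#' @param G Shear modulus (Pa), assumed known and uniform.
#' @return A `force_map` with `method = "laplacian_only"`.
#' @export
laplacian_force_map <- function(field, G) {
  stopifnot(inherits(field, "displacement_field"), G > 0)
  d <- field$dim
  if (any(dim(field$u$uz)[c(d - 1L, d)] < 3L))
    stop("grid too small for central second differences (need >= 3 nodes)")
  h <- field$voxel_size_h
  uz <- field$u$uz
  Fz <- -G * (d2_central(uz, d - 1L, h[d - 1L]) +
                d2_central(uz, d, h[d]))
  new_force_map(Fz, "laplacian_only", field)
}

#' Force map from the full static Navier inversion
#'
#' Recovers the axial force density from all displacement components,
#' \deqn{F = -G \nabla^2 u - \frac{G}{1 - 2\nu} \nabla(\nabla \cdot u),}
#' returning the axial component. Compared to the Laplacian-only map this
#' restores the divergence (pressure-gradient) term, which suppresses the
#' halo artifact around inclusion boundaries.
#'
#' The Laplacian uses the same 3-point central stencil and boundary policy
#' as [laplacian_force_map()]. The divergence term is deliberately not
#' formed by nested nodal central differences: near the incompressible
#' limit its prefactor `G/(1 - 2 nu)` (100 G at nu = 0.495) amplifies any
#' short-wavelength noise in the divergence, and displacement data from
#' near-incompressible solids (including this package's own selectively
#' reduced-integrated elements, whose elementwise pressure admits
#' checkerboard modes) carry exactly such noise. Instead the pseudo-pressure
#' `p = G/(1 - 2 nu) div(u)` is evaluated at cell centers (midpoint-averaged
#' forward differences), averaged onto nodes — the standard checkerboard
#' filter for element-constant pressure — and then differentiated axially
#' with the central stencil.
#'
#' @param field A `displacement_field` with all components.
#' @param G Shear modulus (Pa).
#' @param nu Poisson ratio, strictly below 0.5.
#' @return A `force_map` with `method = "full_navier"`.
#' @export
full_force_map <- function(field, G, nu) {
  stopifnot(inherits(field, "displacement_field"), G > 0)
  if (nu >= 0.5)
    stop("nu must be < 0.5: the divergence factor 1/(1 - 2 nu) is singular")
  d <- field$dim
  h <- field$voxel_size_h
  uz <- field$u$uz
  lap_uz <- Reduce(`+`, lapply(seq_len(d), function(ax)
    d2_central(uz, ax, h[ax])))
  comps <- if (d == 2L) list(field$u$uy, field$u$uz)
           else list(field$u$ux, field$u$uy, field$u$uz)
  beta <- G / (1 - 2 * nu)
  div_e <- Reduce(`+`, lapply(seq_len(d), function(ax)
    elem_center_deriv(comps[[ax]], ax, h[ax])))
  p_node <- elements_to_nodes(beta * div_e, dim(uz))
  ddz_p <- d1_central(p_node, d, h[d])
  new_force_map(-G * lap_uz - ddz_p, "full_navier", field)
}

#' Normalize a force map to unit peak magnitude
#'
#' Divides by the maximum absolute value over valid (non-NA) voxels, so the
#' map's peak magnitude becomes 1 while the sign pattern is preserved.
#' Idempotent.
#'
#' @param map A `force_map`.
#' @return The normalized `force_map` (`normalization = "max_abs"`).
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "force_map"))
  m <- max(abs(map$Fz[is.finite(map$Fz)]))
  if (m == 0) stop("cannot normalize an all-zero force map")
  map$Fz <- map$Fz / m
  map$normalization <- "max_abs"
  map
}

# erode a logical mask by one voxel (face-neighborhood)
erode_mask <- function(mask) {
  out <- mask
  for (ax in seq_along(dim(mask))) {
    for (by in c(-1L, 1L)) {
      nb <- shift_arr(mask + 0, ax, by)
      out <- out & !is.na(nb) & nb > 0
    }
  }
  out
}

#' Mean map intensity over an inclusion mask
#'
#' Arithmetic mean of the force map over the mask voxels. By default the
#' mask is eroded by one voxel first, separating the interior average (the
#' quantity that is proportional to particle density) from the boundary
#' halo overshoot; set `erode = FALSE` for the full-mask mean. Only valid
#' (non-NA) voxels contribute.
#'
#' @param map A `force_map`.
#' @param mask Logical array matching the map grid.
#' @param erode Erode the mask by one voxel before averaging (default TRUE).
#' @return Scalar mean intensity, with attribute `n_voxels`.
#' @export
mean_intensity_in_mask <- function(map, mask, erode = TRUE) {
  stopifnot(inherits(map, "force_map"), is.logical(mask),
            all(dim(mask) == dim(map$Fz)))
  if (!any(mask)) stop("empty mask")
  m <- if (erode) erode_mask(mask) else mask
  vals <- map$Fz[m]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L) stop("mask has no valid (non-NA) voxels")
  structure(mean(vals), n_voxels = length(vals))
}

#' Linearity of recovered intensity versus applied force
#'
#' Ordinary least squares of the recovered mean map intensities on the
#' applied input force densities; proportionality of the two is what makes
#' the force map a quantitative particle-density surrogate.
#'
#' @param input_forces Applied force densities (N/m^3), length >= 3.
#' @param output_means Recovered mean intensities, same length.
#' @return List with `slope`, `intercept`, `r_squared` and
#'   `relative_intercept` (|intercept| relative to the fitted value at the
#'   mean input).
#' @export
linearity_report <- function(input_forces, output_means) {
  stopifnot(length(input_forces) == length(output_means))
  if (length(input_forces) < 3L)
    stop("need at least 3 points for a linearity report")
  fit <- lm(output_means ~ input_forces)
  cf <- coef(fit)
  # exactly proportional data trips summary.lm's perfect-fit warning;
  # that case is a legitimate outcome here, not a misuse
  r2 <- suppressWarnings(summary(fit)$r.squared)
  ref <- abs(cf[2] * mean(input_forces))
  list(slope = unname(cf[2]), intercept = unname(cf[1]), r_squared = r2,
       relative_intercept = unname(abs(cf[1]) / ref))
}

#' Halo-artifact metric
#'
#' Quantifies the overshoot ring around an inclusion boundary: the maximum
#' absolute map value over the background shell (voxels outside the mask
#' but within two inclusion radii of its centroid) divided by the mean
#' absolute value inside the eroded mask. Zero for a perfect recovery
#' (uniform inside, zero outside); invariant under map normalization. The
#' definition is one reasonable instantiation of the visually evident
#' overshoot; no standard quantitative definition exists.
#'
#' @param map A `force_map`.
#' @param inclusion_mask Logical array matching the map grid.
#' @return Scalar halo metric (dimensionless).
#' @export
halo_metric <- function(map, inclusion_mask) {
  stopifnot(inherits(map, "force_map"), is.logical(inclusion_mask),
            all(dim(inclusion_mask) == dim(map$Fz)))
  if (!any(inclusion_mask)) stop("empty inclusion mask")
  d <- length(dim(inclusion_mask))
  ax <- lapply(seq_len(d), function(k)
    axis_coords(map$extent_m[k], map$grid_shape[k]))
  coords <- as.matrix(do.call(expand.grid, ax))
  cen <- colMeans(coords[as.vector(inclusion_mask), , drop = FALSE])
  measure <- sum(inclusion_mask) * prod(map$voxel_size_h)
  r <- if (d == 2L) sqrt(measure / pi) else (3 * measure / (4 * pi))^(1 / 3)
  dist2 <- rowSums(sweep(coords, 2L, cen)^2)
  shell <- array(dist2 <= (2 * r)^2, dim = dim(inclusion_mask)) &
    !inclusion_mask
  shell_vals <- map$Fz[shell]
  shell_vals <- shell_vals[is.finite(shell_vals)]
  if (length(shell_vals) == 0L) stop("degenerate background shell")
  interior <- abs(as.numeric(
    mean_intensity_in_mask(map, inclusion_mask, erode = TRUE)))
  if (interior == 0) stop("zero interior mean; halo metric undefined")
  as.numeric(max(abs(shell_vals)) / interior)
}

#' Convert a force map to a nanoparticle density map
#'
#' Under a uniform axial gradient, the axial force density is
#' `Fz = Mz dBz/dz` with `Mz` the effective magnetization (A/m) of the
#' voxel, so dividing the force map by the gradient turns it into a
#' magnetization-density map; dividing further by the specific saturated
#' moment (A m^2/kg) gives the particle mass density (kg/m^3). This is the
#' sense in which "force map" and "nanoparticle density map" are
#' interchangeable.
#'
#' @param map A `force_map` (values N/m^3).
#' @param gradient Applied axial gradient dBz/dz (T/m, nonzero).
#' @param specific_moment Optional specific moment (A m^2/kg); when given,
#'   `mass_density` is included.
#' @return List with `magnetization_Mz` (array, A/m) and, if requested,
#'   `mass_density` (array, kg/m^3).
#' @export
density_from_force <- function(map, gradient, specific_moment = NULL) {
  stopifnot(inherits(map, "force_map"))
  if (!is.finite(gradient) || gradient == 0)
    stop("gradient must be nonzero to invert Fz = Mz * dBz/dz")
  Mz <- map$Fz / gradient
  out <- list(magnetization_Mz = Mz)
  if (!is.null(specific_moment)) {
    stopifnot(specific_moment > 0)
    out$mass_density <- Mz / specific_moment
  }
  out
}
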