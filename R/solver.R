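#' Forward-solver configuration
#'
#' Settings for the static Navier solve
#' \deqn{G \nabla^2 u + \frac{G}{1 - 2\nu} \nabla(\nabla \cdot u) + F = 0.}
#' The grad-div (divergence) term carries the near-incompressibility: at
#' nu = 0.495 its coefficient is 100 G, which locks plain displacement
#' elements. Both `incompressibility_treatment` values produce the same
#' element operator here: selective reduced integration underintegrates the
#' div-div term with the one-point rule, and a condensed Q1-P0 mixed
#' displacement--pressure element is algebraically identical to that on
#' regular brick elements (the elementwise L2 projection of the trilinear
#' divergence onto constants equals its center-point value).
#'
#' @param formulation `"plane_strain_2d"` (long cylindrical inclusions) or
#'   `"full_3d"`.
#' @param boundary_condition `"bottom_fixed"` (bottom face clamped, the
#'   face the +z body force pushes away from; all other faces
#'   traction-free) or `"all_fixed"` (every boundary node clamped).
#'   Prescribed nonzero boundary displacement can be supplied per solve via
#'   `boundary_values` in [solve_static()].
#' @param linear_solver_tolerance Relative residual for the linear solve,
#'   in (0, 1e-4]. Default 1e-8. 2D systems are solved directly (sparse
#'   Cholesky), 3D iteratively (Jacobi-preconditioned conjugate gradients).
#' @param incompressibility_treatment `"selective_reduced_integration"` or
#'   `"mixed_u_p"` (see Details).
#' @param max_iterations Iteration cap for the 3D conjugate-gradient solve.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(formulation = c("plane_strain_2d", "full_3d"),
                          boundary_condition = c("bottom_fixed", "all_fixed"),
                          linear_solver_tolerance = 1e-8,
                          incompressibility_treatment =
                            c("selective_reduced_integration", "mixed_u_p"),
                          max_iterations = 50000L) {
  formulation <- match.arg(formulation)
  boundary_condition <- match.arg(boundary_condition)
  incompressibility_treatment <- match.arg(incompressibility_treatment)
  stopifnot(linear_solver_tolerance > 0, linear_solver_tolerance <= 1e-4)
  structure(list(formulation = formulation,
                 boundary_condition = boundary_condition,
                 linear_solver_tolerance = linear_solver_tolerance,
                 incompressibility_treatment = incompressibility_treatment,
                 max_iterations = as.integer(max_iterations)),
            class = "solver_config")
}

# --- element stiffness matrices (uniform material, regular grid) ---------

# bilinear quad: corner order (0,0),(1,0),(0,1),(1,1); returns list of
# d/dxi, d/deta rows per node at natural point (xi, eta)
quad_dshape <- function(xi, eta) {
  sx <- c(-1, 1, -1, 1)
  se <- c(-1, -1, 1, 1)
  cbind(sx * (1 + se * eta) / 4, se * (1 + sx * xi) / 4)
}

hex_dshape <- function(xi, eta, zeta) {
  s <- as.matrix(expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1)))
  cbind(s[, 1] * (1 + s[, 2] * eta) * (1 + s[, 3] * zeta) / 8,
        s[, 2] * (1 + s[, 1] * xi) * (1 + s[, 3] * zeta) / 8,
        s[, 3] * (1 + s[, 1] * xi) * (1 + s[, 2] * eta) / 8)
}

# 8x8 Q4 element stiffness for a(u,v) = int G grad(u):grad(v)
#                                     + beta (div u)(div v),
# G term at 2x2 Gauss, div-div term reduced to the center point
quad_stiffness <- function(h, G, beta) {
  detJ <- prod(h) / 4
  Ke <- matrix(0, 8, 8)
  gp <- 1 / sqrt(3)
  for (xi in c(-gp, gp)) for (eta in c(-gp, gp)) {
    dN <- quad_dshape(xi, eta)
    dNx <- sweep(dN, 2, 2 / h, `*`)
    A <- G * tcrossprod(dNx) * detJ
    for (cc in 0:1) {
      idx <- 2 * (0:3) + cc + 1
      Ke[idx, idx] <- Ke[idx, idx] + A
    }
  }
  dNx <- sweep(quad_dshape(0, 0), 2, 2 / h, `*`)
  b <- numeric(8)
  b[2 * (0:3) + 1] <- dNx[, 1]
  b[2 * (0:3) + 2] <- dNx[, 2]
  Ke + beta * prod(h) * tcrossprod(b)
}

# 24x24 trilinear hex element stiffness, same scheme in 3D
hex_stiffness <- function(h, G, beta) {
  detJ <- prod(h) / 8
  Ke <- matrix(0, 24, 24)
  gp <- 1 / sqrt(3)
  for (zeta in c(-gp, gp)) for (eta in c(-gp, gp)) for (xi in c(-gp, gp)) {
    dN <- hex_dshape(xi, eta, zeta)
    dNx <- sweep(dN, 2, 2 / h, `*`)
    A <- G * tcrossprod(dNx) * detJ
    for (cc in 0:2) {
      idx <- 3 * (0:7) + cc + 1
      Ke[idx, idx] <- Ke[idx, idx] + A
    }
  }
  dNx <- sweep(hex_dshape(0, 0, 0), 2, 2 / h, `*`)
  b <- numeric(24)
  for (cc in 1:3) b[3 * (0:7) + cc] <- dNx[, cc]
  Ke + beta * prod(h) * tcrossprod(b)
}

# tributary volumes of grid nodes (trapezoid weights per axis)
tributary_weights <- function(n, h) {
  w <- rep(h, n)
  w[c(1, n)] <- h / 2
  w
}

# node coordinates of a phantom grid as an (nnode x dim) matrix, ordered
# like the flattened arrays (first index fastest)
grid_node_coords <- function(phantom) {
  ax <- lapply(seq_len(phantom$dim), function(k)
    axis_coords(phantom$extent_m[k], phantom$grid_shape[k]))
  as.matrix(do.call(expand.grid, ax))
}

# logical vector over nodes (flattened) that are Dirichlet-constrained
fixed_node_mask <- function(grid_shape, bc) {
  dim <- length(grid_shape)
  idx <- lapply(grid_shape, seq_len)
  g <- do.call(expand.grid, idx)
  if (bc == "bottom_fixed") {
    g[[dim]] == 1L
  } else {
    out <- rep(FALSE, nrow(g))
    for (k in seq_len(dim)) out <- out | g[[k]] == 1L | g[[k]] == grid_shape[k]
    out
  }
}

#' Solve the static Navier equation on a phantom
#'
#' Computes the displacement field induced by the phantom's body-force map
#' by solving the static Navier equation with structured-grid displacement
#' finite elements (bilinear quads in 2D plane strain, trilinear hexes in
#' 3D) and selective reduced integration on the divergence term to avoid
#' volumetric locking at nu near 0.5. 2D systems are solved with a sparse
#' direct factorization; 3D systems with matrix-free Jacobi-preconditioned
#' conjugate gradients.
#'
#' @param phantom A [build_phantom_2d()] / [build_phantom_3d()] phantom.
#' @param config A [solver_config()]; the formulation must match the
#'   phantom dimensionality.
#' @param boundary_values Optional prescribed displacement on the
#'   constrained nodes: a function `f(coords)` taking an (n x dim) matrix
#'   of node coordinates (metres, domain-centered) and returning an
#'   (n x dim) matrix of displacements. Default `NULL` (homogeneous, u = 0).
#' @return An object of class `displacement_field`: displacement component
#'   arrays in `u` (named `uy`, `uz` in 2D; `ux`, `uy`, `uz` in 3D), grid
#'   metadata, the boundary-condition tag, and `solver_info` (method,
#'   iterations, relative residual).
#' @export
solve_static <- function(phantom, config = NULL, boundary_values = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.null(config)) {
    config <- solver_config(
      formulation = if (phantom$dim == 2L) "plane_strain_2d" else "full_3d")
  }
  stopifnot(inherits(config, "solver_config"))
  want <- if (phantom$dim == 2L) "plane_strain_2d" else "full_3d"
  if (config$formulation != want)
    stop(sprintf("config formulation '%s' does not match a %dD phantom",
                 config$formulation, phantom$dim))
  G <- phantom$medium$G
  beta <- G / (1 - 2 * phantom$medium$nu)
  fixed_nodes <- fixed_node_mask(phantom$grid_shape,
                                 config$boundary_condition)
  if (!any(fixed_nodes))
    stop("no constrained boundary: the static system is singular")
  u0_nodes <- NULL
  if (!is.null(boundary_values)) {
    stopifnot(is.function(boundary_values))
    coords <- grid_node_coords(phantom)[fixed_nodes, , drop = FALSE]
    u0_nodes <- boundary_values(coords)
    stopifnot(is.matrix(u0_nodes), nrow(u0_nodes) == sum(fixed_nodes),
              ncol(u0_nodes) == phantom$dim, all(is.finite(u0_nodes)))
  }
  if (phantom$dim == 2L) {
    solve_static_2d(phantom, config, G, beta, fixed_nodes, u0_nodes)
  } else {
    solve_static_3d(phantom, config, G, beta, fixed_nodes, u0_nodes)
  }
}

solve_static_2d <- function(phantom, config, G, beta, fixed_nodes,
                            u0_nodes) {
  ny <- phantom$grid_shape[1]
  nz <- phantom$grid_shape[2]
  h <- phantom$voxel_size_h
  ndof <- 2L * ny * nz
  Ke <- quad_stiffness(h, G, beta)
  # connectivity: element (ey, ez), corners (ey,ez),(ey+1,ez),(ey,ez+1),
  # (ey+1,ez+1) in the Ke corner order
  ey <- rep(seq_len(ny - 1L), nz - 1L)
  ez <- rep(seq_len(nz - 1L), each = ny - 1L)
  n00 <- ey + (ez - 1L) * ny
  nodes <- cbind(n00, n00 + 1L, n00 + ny, n00 + ny + 1L)
  conn <- matrix(0L, nrow(nodes), 8L)
  for (a in 1:4) {
    conn[, 2L * a - 1L] <- 2L * nodes[, a] - 1L
    conn[, 2L * a] <- 2L * nodes[, a]
  }
  pa <- rep(1:8, times = 8)
  pb <- rep(1:8, each = 8)
  K <- Matrix::sparseMatrix(
    i = as.vector(conn[, pa]), j = as.vector(conn[, pb]),
    x = rep(Ke[cbind(pa, pb)], each = nrow(conn)),
    dims = c(ndof, ndof))
  # lumped axial load: nodal force density times tributary area
  trib <- outer(tributary_weights(ny, h[1]), tributary_weights(nz, h[2]))
  f <- numeric(ndof)
  f[2L * seq_len(ny * nz)] <- as.vector(phantom$force_density_Fz * trib)
  fixed_dofs <- rep(fixed_nodes, each = 2L)
  u <- numeric(ndof)
  if (!is.null(u0_nodes)) {
    u0 <- numeric(ndof)
    fn <- which(fixed_nodes)
    u0[2L * fn - 1L] <- u0_nodes[, 1]
    u0[2L * fn] <- u0_nodes[, 2]
    u <- u0
    f <- f - as.numeric(K %*% u0)
  }
  free <- which(!fixed_dofs)
  Kff <- Matrix::forceSymmetric(K[free, free])
  sol <- Matrix::solve(Matrix::Cholesky(Kff, perm = TRUE), f[free])
  u[free] <- as.numeric(sol)
  relres <- sqrt(sum((as.numeric(Kff %*% u[free]) - f[free])^2)) /
    max(sqrt(sum(f[free]^2)), 1e-300)
  new_displacement_field(
    u = list(uy = matrix(u[2L * seq_len(ny * nz) - 1L], ny, nz),
             uz = matrix(u[2L * seq_len(ny * nz)], ny, nz)),
    phantom = phantom, config = config,
    solver_info = list(method = "sparse_cholesky", iterations = 1L,
                       relative_residual = relres))
}

solve_static_3d <- function(phantom, config, G, beta, fixed_nodes,
                            u0_nodes) {
  gs <- phantom$grid_shape
  h <- phantom$voxel_size_h
  nnode <- prod(gs)
  Ke <- hex_stiffness(h, G, beta)
  trib <- outer(outer(tributary_weights(gs[1], h[1]),
                      tributary_weights(gs[2], h[2])),
                tributary_weights(gs[3], h[3]))
  f <- numeric(3L * nnode)
  f[3L * seq_len(nnode)] <- as.vector(phantom$force_density_Fz * trib)
  u0 <- numeric(3L * nnode)
  fn <- which(fixed_nodes)
  if (!is.null(u0_nodes)) {
    u0[3L * fn - 2L] <- u0_nodes[, 1]
    u0[3L * fn - 1L] <- u0_nodes[, 2]
    u0[3L * fn] <- u0_nodes[, 3]
  }
  fixed_idx0 <- as.integer(sort(c(3L * fn - 3L, 3L * fn - 2L, 3L * fn - 1L)))
  res <- .navier3d_cg(f, Ke, gs[1], gs[2], gs[3], fixed_idx0, u0,
                      config$linear_solver_tolerance, config$max_iterations)
  if (!res$converged)
    stop(sprintf(paste0("3D Navier solve did not converge: relative ",
                        "residual %.3g after %d iterations"),
                 res$relative_residual, res$iterations))
  uu <- res$u
  new_displacement_field(
    u = list(ux = array(uu[3L * seq_len(nnode) - 2L], dim = gs),
             uy = array(uu[3L * seq_len(nnode) - 1L], dim = gs),
             uz = array(uu[3L * seq_len(nnode)], dim = gs)),
    phantom = phantom, config = config,
    solver_info = list(method = "jacobi_pcg", iterations = res$iterations,
                       relative_residual = res$relative_residual))
}

new_displacement_field <- function(u, phantom, config, solver_info) {
  structure(list(u = u, voxel_size_h = phantom$voxel_size_h,
                 grid_shape = phantom$grid_shape, dim = phantom$dim,
                 extent_m = phantom$extent_m,
                 boundary_condition_tag = config$boundary_condition,
                 solver_info = solver_info),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("<displacement_field: %dD, %s nodes>\n", x$dim,
              paste(x$grid_shape, collapse = " x ")))
  cat(sprintf("  peak |uz|: %.4g m\n", max(abs(x$u$uz))))
  cat(sprintf("  boundary : %s\n", x$boundary_condition_tag))
  cat(sprintf("  solver   : %s, %d iteration(s), relres %.2g\n",
              x$solver_info$method, x$solver_info$iterations,
              x$solver_info$relative_residual))
  invisible(x)
}

#' Axial strain map
#'
#' Computes the axial normal strain `eps_zz = d(u_z)/dz` by central
#' differences along the axial (last) grid axis, one-sided at the two
#' boundary planes.
#'
#' @param field A `displacement_field`.
#' @return An array (matrix in 2D) of strain values, same shape as the grid.
#' @export
axial_strain <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  uz <- field$u$uz
  hz <- field$voxel_size_h[field$dim]
  d <- field$dim
  n <- dim(uz)[d]
  slice <- function(k) {
    if (d == 2L) uz[, k, drop = FALSE] else uz[, , k, drop = FALSE]
  }
  out <- array(0, dim = dim(uz))
  assign_slice <- function(out, k, val) {
    if (d == 2L) out[, k] <- val else out[, , k] <- val
    out
  }
  out <- assign_slice(out, 1L, (slice(2L) - slice(1L)) / hz)
  out <- assign_slice(out, n, (slice(n) - slice(n - 1L)) / hz)
  for (k in 2:(n - 1L)) {
    out <- assign_slice(out, k, (slice(k + 1L) - slice(k - 1L)) / (2 * hz))
  }
  out
}

#' Calibrate the force density for a target peak strain
#'
#' Elastographic displacement tracking works best at strains of roughly
#' 0.1--1 %. Because the static solve is linear in the load, a single
#' unit-force solve determines the force density giving any target peak
#' axial strain inside the inclusion: the returned value is exact up to
#' solver tolerance, no iteration involved.
#'
#' @param phantom A phantom (its stored `force_density_Fz` is ignored; a
#'   unit load on the inclusion mask is used).
#' @param target_peak_strain Target peak |eps_zz| inside the inclusion
#'   (dimensionless, e.g. 1e-3 for 0.1 %).
#' @param config A [solver_config()] (defaults chosen from the phantom).
#' @return Force density (N/m^3) that produces the target peak strain.
#' @export
calibrate_force_for_peak_strain <- function(phantom, target_peak_strain,
                                            config = NULL) {
  stopifnot(target_peak_strain >= 0)
  if (target_peak_strain == 0) return(0)
  ph1 <- phantom
  ph1$force_density_Fz[ph1$inclusion_mask] <- 1
  fld <- solve_static(ph1, config)
  eps <- axial_strain(fld)
  peak <- max(abs(eps[phantom$inclusion_mask]))
  if (peak == 0) stop("degenerate phantom: unit load produced zero strain")
  target_peak_strain / peak
}

#' Total force for a target peak displacement in a 3D inclusion
#'
#' Builds the 3D spherical-inclusion phantom, runs one unit-force solve and
#' rescales by linearity to the force density producing the target peak
#' axial displacement (10 um is the canonical measurable level for
#' ultrasound elastography); returns the total force, i.e. force density
#' times inclusion volume. Used to regenerate total-force-versus-stiffness
#' and -versus-diameter curves.
#'
#' @param D_mm Sphere diameter (mm).
#' @param E_kPa Young's modulus (kPa).
#' @param target_u_peak Target peak axial displacement (m).
#' @param config A [solver_config()] with `full_3d` formulation (default
#'   built automatically).
#' @param size_cm,grid_n Passed to [build_phantom_3d()].
#' @return Total force (N).
#' @export
total_force_for_peak_displacement <- function(D_mm, E_kPa, target_u_peak,
                                              config = NULL,
                                              size_cm = c(10, 10, 6),
                                              grid_n = c(51L, 51L, 31L)) {
  stopifnot(target_u_peak >= 0)
  if (target_u_peak == 0) return(0)
  ph <- build_phantom_3d(size_cm = size_cm, inclusion_D_mm = D_mm,
                         force_density = 1, E = E_kPa * 1000,
                         grid_n = grid_n)
  fld <- solve_static(ph, config)
  upk <- max(abs(fld$u$uz))
  if (upk == 0) stop("degenerate phantom: unit load produced no displacement")
  fd <- target_u_peak / upk
  fd * sum(ph$inclusion_mask) * prod(ph$voxel_size_h)
}
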