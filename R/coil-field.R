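#' Axial field of a Helmholtz pair
#'
#' Closed-form on-axis flux density of two co-directed loops at
#' `z = +/- d/2`:
#' \deqn{B_z(z) = \frac{\mu_0 n I a^2}{2[(d/2 - z)^2 + a^2]^{3/2}}
#'             + \frac{\mu_0 n I a^2}{2[(d/2 + z)^2 + a^2]^{3/2}}}
#' At the optimal spacing `d = a` the center value is
#' \eqn{(4/5)^{3/2}\,\mu_0 n I/a \approx 0.716\,\mu_0 n I/a}.
#'
#' @param coil A [coil_spec()] with role `"helmholtz"`.
#' @param z Axial position(s) in metres (vectorized).
#' @return Flux density B_z in Tesla, same length as `z`.
#' @export
helmholtz_axial_field <- function(coil, z) {
  stopifnot(inherits(coil, "coil_spec"))
  if (coil$role != "helmholtz")
    stop("helmholtz_axial_field() requires a coil with role 'helmholtz'")
  a <- coil$radius_a
  d <- coil$spacing_d
  k <- MU0 * coil$ampere_turns * a^2 / 2
  k / ((d / 2 - z)^2 + a^2)^1.5 + k / ((d / 2 + z)^2 + a^2)^1.5
}

#' Axial gradient of a Maxwell pair
#'
#' Closed-form on-axis gradient of two opposed loops (top +nI, bottom -nI):
#' \deqn{GR_z(z) = \frac{3 \mu_0 n I a^2}{2}\left[
#'   \frac{d/2 - z}{[(d/2 - z)^2 + a^2]^{5/2}} +
#'   \frac{d/2 + z}{[(d/2 + z)^2 + a^2]^{5/2}}\right]}
#' At the optimal spacing `d = sqrt(3) a` the gradient is maximally flat at
#' the center with value \eqn{0.641\,\mu_0 n I/a^2}.
#'
#' @param coil A [coil_spec()] with role `"maxwell"`.
#' @param z Axial position(s) in metres (vectorized).
#' @return Gradient dBz/dz in Tesla/m, same length as `z`.
#' @export
maxwell_axial_gradient <- function(coil, z) {
  stopifnot(inherits(coil, "coil_spec"))
  if (coil$role != "maxwell")
    stop("maxwell_axial_gradient() requires a coil with role 'maxwell'")
  a <- coil$radius_a
  d <- coil$spacing_d
  k <- 3 * MU0 * coil$ampere_turns * a^2 / 2
  k * ((d / 2 - z) / ((d / 2 - z)^2 + a^2)^2.5 +
       (d / 2 + z) / ((d / 2 + z)^2 + a^2)^2.5)
}

#' Off-axis field of a single circular current loop
#'
#' Full field of one loop of radius `loop_radius` in the plane
#' `z = loop_z`, coaxial with the z-axis, from the standard
#' complete-elliptic-integral solution of the Biot–Savart law. The field is
#' cylindrically symmetric; on the axis it reduces to
#' \eqn{\mu_0 n I a^2 / (2 (a^2 + \zeta^2)^{3/2})}.
#'
#' @param loop_radius Loop radius a (m).
#' @param loop_z Axial position of the loop plane (m).
#' @param ampere_turns Loop excitation n I (A); sign sets current sense.
#' @param point Evaluation point, numeric 3-vector (m), or an n x 3 matrix
#'   of points.
#' @return A numeric 3-vector (Bx, By, Bz) in Tesla, or an n x 3 matrix.
#' @export
loop_field <- function(loop_radius, loop_z, ampere_turns, point) {
  a <- loop_radius
  stopifnot(a > 0, is.finite(loop_z), is.finite(ampere_turns))
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1L)
  stopifnot(ncol(pts) == 3L, all(is.finite(pts)))
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  zeta <- pts[, 3] - loop_z
  # singular on the wire circle itself
  if (any((rho - a)^2 + zeta^2 < (1e-9 * a)^2))
    stop("loop_field(): evaluation point lies on the loop wire (singular)")
  pref <- MU0 * ampere_turns / (2 * pi)
  Brho <- numeric(nrow(pts))
  Bz <- numeric(nrow(pts))
  on_ax <- rho < 1e-12 * a
  if (any(on_ax)) {
    Bz[on_ax] <- MU0 * ampere_turns * a^2 / (2 * (a^2 + zeta[on_ax]^2)^1.5)
  }
  if (any(!on_ax)) {
    r <- rho[!on_ax]
    zz <- zeta[!on_ax]
    alsq <- (a + r)^2 + zz^2
    amsq <- (a - r)^2 + zz^2
    m <- 4 * a * r / alsq            # elliptic parameter m = k^2
    ek <- pracma::ellipke(m)
    K <- ek$k
    E <- ek$e
    Brho[!on_ax] <- pref * zz / (r * sqrt(alsq)) *
      (-K + (a^2 + r^2 + zz^2) / amsq * E)
    Bz[!on_ax] <- pref / sqrt(alsq) *
      (K + (a^2 - r^2 - zz^2) / amsq * E)
  }
  out <- cbind(
    ifelse(rho > 0, pts[, 1] / pmax(rho, 1e-300), 0) * Brho,
    ifelse(rho > 0, pts[, 2] / pmax(rho, 1e-300), 0) * Brho,
    Bz
  )
  colnames(out) <- c("Bx", "By", "Bz")
  if (!is.matrix(point)) out[1, ] else out
}

# Field of both loops of one coil pair at arbitrary points (n x 3 matrix in,
# n x 3 matrix out). Helmholtz: both +nI; Maxwell: top +nI, bottom -nI.
pair_loops_field <- function(coil, pts) {
  s_bot <- if (coil$role == "maxwell") -1 else 1
  loop_field(coil$radius_a, +coil$spacing_d / 2, coil$ampere_turns, pts) +
    loop_field(coil$radius_a, -coil$spacing_d / 2, s_bot * coil$ampere_turns,
               pts)
}

#' Superposed field of the Helmholtz/Maxwell coil pair
#'
#' Sums the off-axis fields of all four loops (two co-directed Helmholtz
#' loops magnetizing the particles, two opposed Maxwell loops providing the
#' gradient) at one point, both pairs coaxial and concentric at the origin.
#' The axial gradient dBz/dz is evaluated by central differences of the
#' elliptic-integral field with step `1e-5 * a` (the closed-form gradient of
#' Eq.-type axial formulas only covers the axis).
#'
#' @param helmholtz A [coil_spec()] with role `"helmholtz"`.
#' @param maxwell A [coil_spec()] with role `"maxwell"`.
#' @param point Numeric 3-vector (m).
#' @return A [field_sample()] with the superposed `B` and `dBz_dz`.
#' @export
pair_field <- function(helmholtz, maxwell, point) {
  stopifnot(inherits(helmholtz, "coil_spec"), inherits(maxwell, "coil_spec"))
  if (helmholtz$role != "helmholtz" || maxwell$role != "maxwell")
    stop("pair_field() needs one helmholtz and one maxwell coil_spec")
  point <- as.numeric(point)
  stopifnot(length(point) == 3L)
  B <- pair_loops_field(helmholtz, matrix(point, 1L)) +
    pair_loops_field(maxwell, matrix(point, 1L))
  h <- 1e-5 * min(helmholtz$radius_a, maxwell$radius_a)
  pp <- point + c(0, 0, h)
  pm <- point - c(0, 0, h)
  Bp <- pair_loops_field(helmholtz, matrix(pp, 1L)) +
    pair_loops_field(maxwell, matrix(pp, 1L))
  Bm <- pair_loops_field(helmholtz, matrix(pm, 1L)) +
    pair_loops_field(maxwell, matrix(pm, 1L))
  field_sample(point, as.numeric(B), (Bp[1, 3] - Bm[1, 3]) / (2 * h))
}

#' Magnetic force on a nanoparticle load
#'
#' Force on a magnetized load from `F = (m . grad) B`. With the moment
#' aligned to z (the Helmholtz field direction), the axial component is
#' `F_z = m_z dBz/dz`. In the saturated regime (|B| at or above the load's
#' saturation field, the regime the imaging system is designed for) the
#' specific moment is the saturation magnetization, so
#' `F_z = saturation_magnetization * weight_w * dBz/dz`; below saturation
#' the moment follows `m = chi H`.
#'
#' @param load A [nanoparticle_load()].
#' @param sample A [field_sample()] at the load position.
#' @param regime `"auto"` (threshold on |B|), `"saturated"` or
#'   `"susceptibility"`.
#' @return Numeric 3-vector force (N); only the axial component is nonzero
#'   (the moment is axial and only dBz/dz is carried by the sample — use
#'   [force_vector_field()] for full off-axis force vectors).
#' @export
force_on_load <- function(load, sample,
                          regime = c("auto", "saturated", "susceptibility")) {
  stopifnot(inherits(load, "nanoparticle_load"),
            inherits(sample, "field_sample"))
  regime <- match.arg(regime)
  Bmag <- sqrt(sum(sample$B^2))
  if (regime == "auto") {
    regime <- if (Bmag >= load$saturation_field_B) "saturated"
              else "susceptibility"
  }
  m_specific <- if (regime == "saturated") {
    load$saturation_magnetization
  } else {
    min(load$susceptibility_chi * Bmag / MU0, load$saturation_magnetization)
  }
  mz <- m_specific * load$weight_w
  c(0, 0, mz * sample$dBz_dz)
}

#' Full force-vector field of the coil pair
#'
#' Evaluates `F = (m . grad) B` at a set of points with the moment locked to
#' the local field direction at saturated magnitude (the Helmholtz field
#' dominates, so the moment is essentially axial in the imaging region). The
#' directional derivative is computed by central differences of the
#' elliptic-integral loop fields with step `1e-5 * a`.
#'
#' @param helmholtz,maxwell [coil_spec()] objects with matching roles.
#' @param load A [nanoparticle_load()].
#' @param points n x 3 matrix of evaluation points (m).
#' @return n x 3 matrix of force vectors (N).
#' @export
force_vector_field <- function(helmholtz, maxwell, load, points) {
  stopifnot(is.matrix(points), ncol(points) == 3L)
  Bfun <- function(p) pair_loops_field(helmholtz, p) +
    pair_loops_field(maxwell, p)
  B <- Bfun(points)
  Bmag <- sqrt(rowSums(B^2))
  mhat <- B / pmax(Bmag, 1e-300)
  m <- load$saturation_magnetization * load$weight_w
  h <- 1e-5 * min(helmholtz$radius_a, maxwell$radius_a)
  F <- matrix(0, nrow(points), 3L)
  for (ax in 1:3) {
    dp <- matrix(0, nrow(points), 3L)
    dp[, ax] <- h
    dB <- (Bfun(points + dp) - Bfun(points - dp)) / (2 * h)
    F <- F + (m * mhat[, ax]) * dB
  }
  colnames(F) <- c("Fx", "Fy", "Fz")
  F
}

#' Ampere-turns for a target Helmholtz center field
#'
#' Inverts the optimal-spacing (`d = a`) center-field formula
#' \eqn{B_z(0) = (4/5)^{3/2} \mu_0 n I / a} for the excitation needed to
#' magnetize the nanoparticles, e.g. 0.4 T to saturate typical iron-oxide
#' particles.
#'
#' @param target_B Desired center flux density (T, > 0; 0 allowed and
#'   returns 0).
#' @param radius_a Coil radius (m, > 0).
#' @return Required ampere-turns n I (A).
#' @examples
#' required_helmholtz_ampere_turns(0.4, 0.075)  # ~ 3.34e4 A
#' @export
required_helmholtz_ampere_turns <- function(target_B, radius_a) {
  stopifnot(is.numeric(target_B), length(target_B) == 1L, target_B >= 0,
            is.numeric(radius_a), length(radius_a) == 1L, radius_a > 0)
  target_B * radius_a / (helmholtz_center_coefficient() * MU0)
}

#' Ampere-turns for a target axial force on a saturated load
#'
#' Inverts the optimal-spacing (`d = sqrt(3) a`) Maxwell center-gradient
#' formula: with a saturated load,
#' \eqn{F_z(0) = M_{sat} w \cdot 0.641\, \mu_0 n I / a^2}, so
#' \eqn{n I = F_z a^2 / (M_{sat} w \cdot 0.641\, \mu_0)}. Used to size the
#' gradient-coil drive for measurable tissue displacement (forces of order
#' 10--40 mN for gram-scale deposits).
#'
#' @param target_force Desired axial force (N, >= 0).
#' @param load A [nanoparticle_load()] with positive weight.
#' @param radius_a Coil radius (m, > 0).
#' @return Required ampere-turns n I (A).
#' @export
required_maxwell_ampere_turns <- function(target_force, load, radius_a) {
  stopifnot(inherits(load, "nanoparticle_load"),
            is.numeric(target_force), length(target_force) == 1L,
            target_force >= 0, radius_a > 0)
  if (load$weight_w <= 0)
    stop("required_maxwell_ampere_turns(): load weight is zero; ",
         "no finite current produces force on an empty load")
  target_force * radius_a^2 /
    (load$saturation_magnetization * load$weight_w *
       maxwell_center_coefficient() * MU0)
}

#' Force uniformity over the imaging volume
#'
#' Samples the axial force (per unit saturated moment, i.e. dBz/dz up to a
#' constant) of the coil pair over the cubic imaging region of side `2a/3`
#' centered at the origin, and reports the maximum relative deviation from
#' the center value together with the axial profile. Uniform gradient over
#' the region of interest is what makes the recovered force map proportional
#' to particle density, so this report quantifies how well the pair
#' approximates that.
#'
#' The report carries two views. The full-pair view differentiates the
#' superposed field of all four loops; off-center the Helmholtz pair's own
#' field gradient contributes (it only vanishes exactly at the center), so
#' at typical excitation ratios (Helmholtz ampere-turns well above the
#' Maxwell ones, as needed for saturation) the full-pair force deviates
#' strongly toward the cube faces. The gradient-only view uses the Maxwell
#' pair alone — the design idealization in which the Helmholtz coil is a
#' pure magnetizer — and is flat to a few percent over the cube at optimal
#' spacing.
#'
#' @param helmholtz,maxwell [coil_spec()] objects with matching roles.
#' @param grid_n Samples per axis (>= 3).
#' @return An object of class `uniformity_report`: list with `side_m`,
#'   `center_value` (T/m), `max_relative_deviation` (full pair, over the
#'   cube), `max_axial_deviation_gradient_only` (Maxwell pair alone, on
#'   axis), `axial_profile` (data.frame z, dBz_dz, relative_deviation,
#'   dBz_dz_maxwell_only, relative_deviation_maxwell_only) and `grid_n`.
#' @export
imaging_volume_uniformity <- function(helmholtz, maxwell, grid_n = 11L) {
  stopifnot(grid_n >= 3L)
  a <- min(helmholtz$radius_a, maxwell$radius_a)
  side <- 2 * a / 3
  h <- 1e-5 * a
  gz <- function(pts) {  # vectorized dBz/dz of the superposed pair
    shift <- function(s) {
      p <- pts
      p[, 3] <- p[, 3] + s
      pair_loops_field(helmholtz, p)[, 3] + pair_loops_field(maxwell, p)[, 3]
    }
    (shift(h) - shift(-h)) / (2 * h)
  }
  center <- gz(matrix(0, 1L, 3L))
  xs <- seq(-side / 2, side / 2, length.out = grid_n)
  grid <- as.matrix(expand.grid(x = xs, y = xs, z = xs))
  vals <- gz(grid)
  dev <- abs(vals - center) / abs(center)
  zs <- xs
  prof_vals <- gz(cbind(0, 0, zs))
  grad_only <- maxwell_axial_gradient(maxwell, zs)
  grad_center <- maxwell_axial_gradient(maxwell, 0)
  structure(list(
    side_m = side,
    center_value = center,
    max_relative_deviation = max(dev),
    max_axial_deviation_gradient_only =
      max(abs(grad_only - grad_center) / abs(grad_center)),
    axial_profile = data.frame(
      z = zs, dBz_dz = prof_vals,
      relative_deviation = abs(prof_vals - center) / abs(center),
      dBz_dz_maxwell_only = grad_only,
      relative_deviation_maxwell_only =
        abs(grad_only - grad_center) / abs(grad_center)),
    grid_n = grid_n
  ), class = "uniformity_report")
}

#' @export
print.uniformity_report <- function(x, ...) {
  cat("<uniformity_report>\n")
  cat(sprintf("  imaging cube side               : %g m (2a/3)\n", x$side_m))
  cat(sprintf("  center dBz/dz                   : %.4g T/m\n",
              x$center_value))
  cat(sprintf("  max relative deviation (pair)   : %.3f%%\n",
              100 * x$max_relative_deviation))
  cat(sprintf("  max axial deviation (grad only) : %.3f%%\n",
              100 * x$max_axial_deviation_gradient_only))
  invisible(x)
}
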