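#' Kelvin solution for a uniformly loaded ball
#'
#' Closed-form displacement of an infinite linear-elastic medium loaded by
#' a uniform axial body-force density `f` inside a ball of radius `R` —
#' the superposition (convolution) of the Kelvin point-force solution
#' \deqn{u_i(x) = \frac{F_j}{16 \pi G (1-\nu)}
#'   \left[(3-4\nu)\frac{\delta_{ij}}{r} + \frac{x_i x_j}{r^3}\right]}
#' over the ball. These serve as the analytic oracle for the 3D forward
#' solver: `kelvin_ball_center_uz()` gives the axial displacement at the
#' ball center,
#' \deqn{u_z(0) = \frac{f R^2 (5 - 6\nu)}{12 G (1-\nu)},}
#' and `kelvin_ball_displacement()` the full displacement vector at points
#' strictly outside the ball,
#' \deqn{u_i(x) = \frac{f V}{16 \pi G (1-\nu)} \left[
#'   (3-4\nu)\frac{\delta_{iz}}{s} + \frac{x_i z}{s^3}
#'   + \frac{R^2}{5}\left(\frac{\delta_{iz}}{s^3}
#'   - \frac{3 x_i z}{s^5}\right) \right]}
#' with `V` the ball volume and `s = |x|` — the equivalent point force plus
#' the finite-size correction. Both forms follow from the Newtonian
#' potentials of the ball (`1/s` and `s` convolved over the ball have the
#' closed forms `V/s` and `V (s + R^2/(5 s))` outside it).
#'
#' @param force_density Axial body-force density f inside the ball (N/m^3).
#' @param radius Ball radius R (m).
#' @param G Shear modulus (Pa).
#' @param nu Poisson ratio (< 0.5).
#' @return `kelvin_ball_center_uz()`: scalar axial displacement (m).
#' @export
kelvin_ball_center_uz <- function(force_density, radius, G, nu) {
  stopifnot(radius > 0, G > 0, nu < 0.5)
  force_density * radius^2 * (5 - 6 * nu) / (12 * G * (1 - nu))
}

#' @rdname kelvin_ball_center_uz
#' @param points n x 3 matrix of evaluation points (m), ball-centered
#'   coordinates, all strictly outside the ball.
#' @return `kelvin_ball_displacement()`: n x 3 matrix of displacement
#'   vectors (m).
#' @export
kelvin_ball_displacement <- function(points, force_density, radius, G, nu) {
  stopifnot(is.matrix(points), ncol(points) == 3L, radius > 0, G > 0,
            nu < 0.5)
  s2 <- rowSums(points^2)
  if (any(s2 <= radius^2))
    stop("kelvin_ball_displacement() is the exterior solution: ",
         "all points must lie strictly outside the ball")
  s <- sqrt(s2)
  V <- 4 / 3 * pi * radius^3
  C <- force_density * V / (16 * pi * G * (1 - nu))
  z <- points[, 3]
  common <- C * (z / s^3 - (radius^2 / 5) * 3 * z / s^5)
  u <- points * common
  u[, 3] <- u[, 3] + C * ((3 - 4 * nu) / s + (radius^2 / 5) / s^3)
  colnames(u) <- c("ux", "uy", "uz")
  u
}
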