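#' Specify one coaxial coil pair
#'
#' A coil pair is two circular loops of radius `radius_a`, coaxial with the
#' z-axis, centered at `z = -spacing_d/2` and `z = +spacing_d/2`, each carrying
#' `ampere_turns` (the product of turns and current, n I). The `role`
#' determines the current sense: a `"helmholtz"` pair drives both loops in the
#' same direction (uniform field at the center); a `"maxwell"` pair drives
#' them in opposition (top loop +nI, bottom loop -nI; linear axial gradient,
#' zero field at the center).
#'
#' @param radius_a Loop radius in metres (> 0).
#' @param ampere_turns Excitation n I in Ampere-turns (finite).
#' @param spacing_d Loop interspacing in metres (> 0). Defaults to the
#'   optimal spacing for the role: `d = a` for Helmholtz (maximally uniform
#'   field), `d = sqrt(3) a` for Maxwell (maximally linear gradient).
#' @param role `"helmholtz"` or `"maxwell"`.
#' @return An object of class `coil_spec`.
#' @examples
#' helmholtz_coil(0.075, 1e4)
#' maxwell_coil(0.075, 1e3)
#' @export
coil_spec <- function(radius_a, ampere_turns,
                      spacing_d = NULL,
                      role = c("helmholtz", "maxwell")) {
  role <- match.arg(role)
  if (is.null(spacing_d)) {
    spacing_d <- if (role == "helmholtz") radius_a else sqrt(3) * radius_a
  }
  stopifnot(is.numeric(radius_a), length(radius_a) == 1L, is.finite(radius_a),
            is.numeric(spacing_d), length(spacing_d) == 1L, is.finite(spacing_d),
            is.numeric(ampere_turns), length(ampere_turns) == 1L,
            is.finite(ampere_turns))
  if (radius_a <= 0) stop("coil radius must be positive")
  if (spacing_d <= 0) stop("coil spacing must be positive")
  structure(list(radius_a = radius_a, spacing_d = spacing_d,
                 ampere_turns = ampere_turns, role = role),
            class = "coil_spec")
}

#' @rdname coil_spec
#' @export
helmholtz_coil <- function(radius_a, ampere_turns, spacing_d = radius_a) {
  coil_spec(radius_a, ampere_turns, spacing_d, role = "helmholtz")
}

#' @rdname coil_spec
#' @export
maxwell_coil <- function(radius_a, ampere_turns,
                         spacing_d = sqrt(3) * radius_a) {
  coil_spec(radius_a, ampere_turns, spacing_d, role = "maxwell")
}

#' @export
print.coil_spec <- function(x, ...) {
  cat(sprintf("<coil_spec: %s pair>\n", x$role))
  cat(sprintf("  radius a       : %g m\n", x$radius_a))
  cat(sprintf("  spacing d      : %g m (%s)\n", x$spacing_d,
              if (isTRUE(all.equal(x$spacing_d,
                                   if (x$role == "helmholtz") x$radius_a
                                   else sqrt(3) * x$radius_a)))
                "optimal" else "non-optimal"))
  cat(sprintf("  ampere-turns nI: %g A\n", x$ampere_turns))
  invisible(x)
}

#' Nanoparticle load at a pixel or region of interest
#'
#' Describes the magnetic payload whose force response is being mapped.
#' Superparamagnetic nanoparticles magnetize with the applied field and
#' saturate at roughly 0.2--0.5 T; above saturation the specific moment per
#' unit particle mass is `saturation_magnetization` (typically 20--40 A m^2/kg
#' for iron-oxide particles), below it the moment follows m = chi H.
#'
#' @param saturation_magnetization Specific saturated moment, A m^2 per kg
#'   of particles (>= 0). Default 20.
#' @param susceptibility_chi Mass susceptibility used below saturation, in
#'   m^3/kg (so that specific moment = chi * H with H in A/m). Default 0
#'   (particles treated as fully saturated).
#' @param weight_w Particle mass deposited in the region of interest, kg.
#' @param saturation_field_B Flux density (T) above which the load is
#'   considered saturated. Default 0.4.
#' @return An object of class `nanoparticle_load`.
#' @export
nanoparticle_load <- function(saturation_magnetization = 20,
                              susceptibility_chi = 0,
                              weight_w = 1e-3,
                              saturation_field_B = 0.4) {
  stopifnot(is.numeric(saturation_magnetization),
            saturation_magnetization >= 0,
            is.numeric(susceptibility_chi), susceptibility_chi >= 0,
            is.numeric(weight_w), weight_w >= 0,
            is.numeric(saturation_field_B), saturation_field_B > 0)
  structure(list(saturation_magnetization = saturation_magnetization,
                 susceptibility_chi = susceptibility_chi,
                 weight_w = weight_w,
                 saturation_field_B = saturation_field_B),
            class = "nanoparticle_load")
}

#' @export
print.nanoparticle_load <- function(x, ...) {
  cat("<nanoparticle_load>\n")
  cat(sprintf("  saturation magnetization: %g A m^2/kg\n",
              x$saturation_magnetization))
  cat(sprintf("  mass susceptibility     : %g m^3/kg\n", x$susceptibility_chi))
  cat(sprintf("  weight                  : %g kg\n", x$weight_w))
  cat(sprintf("  saturation field        : %g T\n", x$saturation_field_B))
  invisible(x)
}

#' A sampled field point
#'
#' Bundles position, magnetic flux density vector and the axial gradient
#' dBz/dz at one point — the quantities the force model consumes.
#'
#' @param position 3-vector (m).
#' @param B 3-vector flux density (T).
#' @param dBz_dz Axial gradient of the axial component (T/m).
#' @return An object of class `field_sample`.
#' @export
field_sample <- function(position, B, dBz_dz) {
  stopifnot(length(position) == 3L, length(B) == 3L, length(dBz_dz) == 1L,
            all(is.finite(position)), all(is.finite(B)), is.finite(dBz_dz))
  structure(list(position = as.numeric(position), B = as.numeric(B),
                 dBz_dz = as.numeric(dBz_dz)),
            class = "field_sample")
}

#' @export
print.field_sample <- function(x, ...) {
  cat("<field_sample>\n")
  cat(sprintf("  position: (%g, %g, %g) m\n", x$position[1], x$position[2],
              x$position[3]))
  cat(sprintf("  B       : (%.4g, %.4g, %.4g) T\n", x$B[1], x$B[2], x$B[3]))
  cat(sprintf("  dBz/dz  : %.4g T/m\n", x$dBz_dz))
  invisible(x)
}
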