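#' Configure a scripted experiment
#'
#' The experiments are self-contained reproductions of the pipeline's
#' headline results: coil coefficients and current requirements, the 2D
#' displacement/strain/force maps for single and double inclusions, the
#' divergence-term comparison, the intensity-vs-force linearity sweep, and
#' the 3D total-force calculations. Every run resolves its full parameter
#' set (defaults merged with `overrides`) and reports it alongside the
#' metrics, so any run can be reproduced exactly.
#'
#' @param experiment_id One of `"coefficients"`, `"single_inclusion_maps"`,
#'   `"double_inclusion_maps"`, `"divergence_comparison"`, `"linearity_sweep"`,
#'   `"total_force_sweep"`, `"coil_currents"`.
#' @param overrides Named list of parameter overrides (see each runner's
#'   defaults in the report's `params`).
#' @param seed Integer seed; experiments are deterministic under it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment_id, overrides = list(), seed = 1L) {
  ids <- c("coefficients", "single_inclusion_maps", "double_inclusion_maps",
           "divergence_comparison", "linearity_sweep", "total_force_sweep",
           "coil_currents")
  if (!experiment_id %in% ids)
    stop("unknown experiment_id; valid ids: ", paste(ids, collapse = ", "))
  stopifnot(is.list(overrides))
  structure(list(experiment_id = experiment_id, overrides = overrides,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

merge_params <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' Run a scripted experiment
#'
#' Executes the pipeline for one experiment id (phantom construction,
#' forward solve, inversion and metrics — or the coil calculations) and
#' returns a report bundle. When `out_dir` is given, the resolved
#' parameters (YAML), metric tables (CSV) and maps (MHD volumes and PNG
#' heatmaps) are written there.
#'
#' @param config An [experiment_config()], or an experiment id string.
#' @param out_dir Optional output directory (created if missing).
#' @return An `experiment_report`: list with `experiment_id`, `params`,
#'   `metrics` (named numerics), `tables` (data.frames) and `maps`
#'   (force-map / matrix objects), depending on the experiment.
#' @examples
#' rep <- run_experiment("coefficients")
#' rep$tables$coefficients
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  runner <- switch(config$experiment_id,
    coefficients = run_coefficients,
    single_inclusion_maps = run_single_inclusion_maps,
    double_inclusion_maps = run_double_inclusion_maps,
    divergence_comparison = run_divergence_comparison,
    linearity_sweep = run_linearity_sweep,
    total_force_sweep = run_total_force_sweep,
    coil_currents = run_current_requirements)
  report <- tryCatch(
    runner(config$overrides),
    error = function(e) stop(sprintf("experiment '%s' failed: %s",
                                     config$experiment_id, conditionMessage(e)),
                             call. = FALSE))
  report$experiment_id <- config$experiment_id
  report$seed <- config$seed
  class(report) <- "experiment_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report: %s>\n", x$experiment_id))
  if (length(x$metrics)) {
    cat("  metrics:\n")
    for (nm in names(x$metrics))
      cat(sprintf("    %-28s %s\n", nm, format(signif(x$metrics[[nm]], 6))))
  }
  if (length(x$tables))
    cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  if (length(x$maps))
    cat("  maps  :", paste(names(x$maps), collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, report$experiment_id)
  write_sidecar(c(list(experiment_id = report$experiment_id,
                       seed = report$seed), report$params),
                paste0(pre, "_params.yaml"))
  if (length(report$metrics)) {
    writeLines(sprintf("%s: %.10g", names(report$metrics),
                       unlist(report$metrics)),
               paste0(pre, "_metrics.txt"))
  }
  for (nm in names(report$tables))
    write.csv(report$tables[[nm]], paste0(pre, "_", nm, ".csv"),
              row.names = FALSE)
  for (nm in names(report$maps)) {
    m <- report$maps[[nm]]
    arr <- if (inherits(m, "force_map")) m$Fz else m
    if (length(dim(arr)) %in% c(2L, 3L)) {
      sp <- if (inherits(m, "force_map")) m$voxel_size_h else 1
      write_mhd(ifelse(is.finite(arr), arr, 0), paste0(pre, "_", nm), sp)
      if (length(dim(arr)) == 2L) {
        ext <- if (inherits(m, "force_map")) m$extent_m
               else c(1, 1) * max(dim(arr))
        render_maps(arr, paste0(pre, "_", nm, ".png"), extent_m = ext,
                    title = nm)
      }
    }
  }
  invisible(out_dir)
}

# shared 2D pipeline: build phantom, calibrate to target peak strain,
# solve, return everything downstream stages need
pipeline_2d <- function(inclusions, params) {
  ph <- build_phantom_2d(side_cm = params$side_cm, inclusions = inclusions,
                         E = params$E, nu = params$nu,
                         grid_n = params$grid_n)
  f_cal <- calibrate_force_for_peak_strain(ph, params$target_peak_strain)
  ph$force_density_Fz[ph$inclusion_mask] <- f_cal
  for (i in seq_along(ph$inclusions))
    ph$inclusions[[i]]$force_density <- f_cal
  fld <- solve_static(ph)
  list(phantom = ph, field = fld, force_density = f_cal,
       G = ph$medium$G, nu = ph$medium$nu)
}

single_inclusion_spec <- function(params) {
  list(list(center = c(0, 0), diameter = params$D_mm / 1000,
            force_density = 1))
}

double_inclusion_spec <- function(params) {
  s <- params$separation_m / 2
  list(list(center = c(-s, 0), diameter = params$D_big_mm / 1000,
            force_density = 1),
       list(center = c(s, 0), diameter = params$D_small_mm / 1000,
            force_density = 1))
}

default_2d_params <- function() {
  list(side_cm = 10, grid_n = 201L, E = 10e3, nu = 0.495,
       target_peak_strain = 1e-3, D_mm = 10,
       D_big_mm = 10, D_small_mm = 5, separation_m = 0.025)
}

inclusion_masks <- function(ph) {
  ys <- axis_coords(ph$extent_m[1], ph$grid_shape[1])
  zs <- axis_coords(ph$extent_m[2], ph$grid_shape[2])
  lapply(ph$inclusions, function(inc) {
    d2 <- outer((ys - inc$center[1])^2, (zs - inc$center[2])^2, `+`)
    d2 < (inc$diameter / 2)^2
  })
}

run_coefficients <- function(overrides) {
  params <- merge_params(list(radius_a = 0.075,
                              saturation_magnetization = 20), overrides)
  a <- params$radius_a
  hh <- helmholtz_coil(a, 1)
  mx <- maxwell_coil(a, 1)
  c_h <- helmholtz_axial_field(hh, 0) * a / MU0
  c_m <- maxwell_axial_gradient(mx, 0) * a^2 / MU0
  load <- nanoparticle_load(params$saturation_magnetization, weight_w = 1)
  Fz <- force_on_load(load, field_sample(c(0, 0, 0), c(0, 0, 0.4),
                                         maxwell_axial_gradient(mx, 0)),
                      regime = "saturated")[3]
  c_f <- Fz * a^2 / MU0  # coefficient of w mu0 nI / a^2 (w = nI = 1)
  list(params = params,
       tables = list(coefficients = data.frame(
         quantity = c("helmholtz_center_field", "maxwell_center_gradient",
                      "saturated_force"),
         coefficient = c(c_h, c_m, c_f),
         unit = c("mu0*n1*I1/a", "mu0*n2*I2/a^2", "w*mu0*n2*I2/a^2"))),
       metrics = list(helmholtz_coefficient = c_h,
                      maxwell_coefficient = c_m,
                      force_coefficient = c_f))
}

run_single_inclusion_maps <- function(overrides) {
  params <- merge_params(default_2d_params(), overrides)
  pl <- pipeline_2d(single_inclusion_spec(params), params)
  eps <- axial_strain(pl$field)
  ml <- laplacian_force_map(pl$field, pl$G)
  mask <- pl$phantom$inclusion_mask
  list(params = params,
       metrics = list(
         calibrated_force_density = pl$force_density,
         peak_uz = max(abs(pl$field$u$uz)),
         peak_strain = max(abs(eps[mask])),
         interior_mean_laplacian = as.numeric(
           mean_intensity_in_mask(ml, mask)),
         halo_laplacian = halo_metric(ml, mask)),
       maps = list(uz = pl$field$u$uz, strain = eps, force_laplacian = ml))
}

run_double_inclusion_maps <- function(overrides) {
  params <- merge_params(default_2d_params(), overrides)
  pl <- pipeline_2d(double_inclusion_spec(params), params)
  eps <- axial_strain(pl$field)
  ml <- laplacian_force_map(pl$field, pl$G)
  masks <- inclusion_masks(pl$phantom)
  list(params = params,
       metrics = list(
         calibrated_force_density = pl$force_density,
         peak_uz = max(abs(pl$field$u$uz)),
         interior_mean_big = as.numeric(
           mean_intensity_in_mask(ml, masks[[1]])),
         interior_mean_small = as.numeric(
           mean_intensity_in_mask(ml, masks[[2]])),
         mask_area_ratio = sum(masks[[1]]) / sum(masks[[2]])),
       maps = list(uz = pl$field$u$uz, strain = eps, force_laplacian = ml))
}

run_divergence_comparison <- function(overrides) {
  params <- merge_params(default_2d_params(), overrides)
  pl <- pipeline_2d(single_inclusion_spec(params), params)
  mf <- full_force_map(pl$field, pl$G, pl$nu)
  ml <- laplacian_force_map(pl$field, pl$G)
  mask <- pl$phantom$inclusion_mask
  iy <- (pl$phantom$grid_shape[1] + 1L) %/% 2L
  zs <- axis_coords(pl$phantom$extent_m[2], pl$phantom$grid_shape[2])
  cuts <- data.frame(z_m = zs,
                     with_divergence = normalize_map(mf)$Fz[iy, ],
                     without_divergence = normalize_map(ml)$Fz[iy, ])
  list(params = params,
       metrics = list(
         halo_with_divergence = halo_metric(mf, mask),
         halo_without_divergence = halo_metric(ml, mask),
         interior_mean_with = as.numeric(mean_intensity_in_mask(mf, mask)),
         interior_mean_without = as.numeric(
           mean_intensity_in_mask(ml, mask)),
         applied_force_density = pl$force_density),
       tables = list(cut_views = cuts),
       maps = list(force_with_divergence = normalize_map(mf),
                   force_without_divergence = normalize_map(ml)))
}

run_linearity_sweep <- function(overrides) {
  params <- merge_params(c(default_2d_params(),
                           list(level_factors = seq(0.5, 1.5,
                                                    length.out = 5))),
                         overrides)
  ph <- build_phantom_2d(side_cm = params$side_cm,
                         inclusions = single_inclusion_spec(params),
                         E = params$E, nu = params$nu,
                         grid_n = params$grid_n)
  f_cal <- calibrate_force_for_peak_strain(ph, params$target_peak_strain)
  levels <- f_cal * params$level_factors
  mask <- ph$inclusion_mask
  means <- vapply(levels, function(f) {
    phi <- ph
    phi$force_density_Fz[mask] <- f
    fld <- solve_static(phi)
    as.numeric(mean_intensity_in_mask(laplacian_force_map(fld, ph$medium$G),
                                      mask))
  }, numeric(1))
  fit <- linearity_report(levels, means)
  list(params = params,
       metrics = list(r_squared = fit$r_squared, slope = fit$slope,
                      intercept = fit$intercept,
                      relative_intercept = fit$relative_intercept),
       tables = list(sweep = data.frame(input_force = levels,
                                        mean_intensity = means)))
}

run_total_force_sweep <- function(overrides) {
  params <- merge_params(list(
    D_mm = c(10, 20, 30, 40), E_kPa = c(5, 10, 20, 30),
    D_fixed_mm = 20, E_fixed_kPa = 10, target_u_peak = 10e-6,
    size_cm = c(10, 10, 6), grid_n = c(35L, 35L, 21L)), overrides)
  by_D <- vapply(params$D_mm, function(D)
    total_force_for_peak_displacement(D, params$E_fixed_kPa,
                                      params$target_u_peak,
                                      size_cm = params$size_cm,
                                      grid_n = params$grid_n), numeric(1))
  by_E <- vapply(params$E_kPa, function(E)
    total_force_for_peak_displacement(params$D_fixed_mm, E,
                                      params$target_u_peak,
                                      size_cm = params$size_cm,
                                      grid_n = params$grid_n), numeric(1))
  list(params = params,
       metrics = list(
         force_ratio_maxmin_over_D = max(by_D) / min(by_D),
         force_per_E_spread = max(by_E / params$E_kPa) /
           min(by_E / params$E_kPa)),
       tables = list(
         by_diameter = data.frame(D_mm = params$D_mm, total_force_N = by_D,
                                  E_kPa = params$E_fixed_kPa),
         by_stiffness = data.frame(E_kPa = params$E_kPa,
                                   total_force_N = by_E,
                                   D_mm = params$D_fixed_mm)))
}

run_current_requirements <- function(overrides) {
  params <- merge_params(list(
    radius_a = 0.075, target_B = 0.4, saturation_magnetization = 20,
    forces_mN = c(10, 20, 30, 40), weights_g = c(0.25, 0.5, 0.75, 1)),
    overrides)
  nI_h <- required_helmholtz_ampere_turns(params$target_B, params$radius_a)
  grid <- expand.grid(force_mN = params$forces_mN,
                      weight_g = params$weights_g)
  grid$maxwell_ampere_turns <- mapply(function(f, w)
    required_maxwell_ampere_turns(
      f / 1000, nanoparticle_load(params$saturation_magnetization,
                                  weight_w = w / 1000),
      params$radius_a),
    grid$force_mN, grid$weight_g)
  list(params = params,
       metrics = list(helmholtz_ampere_turns = nI_h),
       tables = list(maxwell_currents = grid))
}

#' Render a map as a PNG image
#'
#' Writes a heatmap of a 2D scalar map (with colorbar and physical axes in
#' cm) or an arrow plot of a vector field. Rendering identical data with
#' identical style produces identical images.
#'
#' @param x For `style = "heatmap"`: a `force_map` or numeric matrix. For
#'   `style = "vectors"`: a data.frame with columns `y`, `z`, `Fy`, `Fz`
#'   (positions in m, vector components in any common unit).
#' @param file Output PNG path.
#' @param style `"heatmap"` or `"vectors"`.
#' @param extent_m Physical extents (m) for matrix input; taken from the
#'   `force_map` otherwise.
#' @param title Plot title.
#' @return Invisibly, `file`.
#' @export
render_maps <- function(x, file, style = c("heatmap", "vectors"),
                        extent_m = NULL, title = "") {
  style <- match.arg(style)
  grDevices::png(file, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  if (style == "heatmap") {
    if (inherits(x, "force_map")) {
      extent_m <- x$extent_m
      x <- x$Fz
    }
    stopifnot(is.matrix(x))
    if (is.null(extent_m)) extent_m <- c(1, 1)
    ys <- 100 * axis_coords(extent_m[1], nrow(x))
    zs <- 100 * axis_coords(extent_m[2], ncol(x))
    vals <- ifelse(is.finite(x), x, 0)
    rng <- range(vals)
    if (rng[1] == rng[2]) rng <- rng + c(-1, 1) * max(abs(rng[1]), 1e-12)
    pal <- grDevices::hcl.colors(64, "viridis")
    graphics::layout(matrix(1:2, 1), widths = c(5, 1))
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::image(ys, zs, vals, col = pal, zlim = rng,
                    xlab = "y [cm]", ylab = "z [cm]", main = title,
                    useRaster = TRUE)
    graphics::par(mar = c(4, 1, 3, 3))
    graphics::image(1, seq(rng[1], rng[2], length.out = 64),
                    matrix(seq(rng[1], rng[2], length.out = 64), 1),
                    col = pal, xaxt = "n", xlab = "", ylab = "")
  } else {
    stopifnot(is.data.frame(x), all(c("y", "z", "Fy", "Fz") %in% names(x)))
    mag <- sqrt(x$Fy^2 + x$Fz^2)
    scl <- 0.4 * max(diff(range(x$y)), diff(range(x$z))) /
      (sqrt(length(mag)) * max(mag, 1e-300))
    graphics::par(mar = c(4, 4, 3, 1))
    graphics::plot(100 * x$y, 100 * x$z, type = "n", xlab = "y [cm]",
                   ylab = "z [cm]", main = title, asp = 1)
    graphics::arrows(100 * x$y, 100 * x$z, 100 * (x$y + scl * x$Fy),
                     100 * (x$z + scl * x$Fz), length = 0.04)
  }
  invisible(file)
}
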