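#' Parameters of the synthetic ablation phantom
#'
#' Defines one synthetic ablation: an ellipsoidal white zone (half-length
#' `a` along the antenna, radial half-width `b`) carrying a vessel-side
#' indentation whose depth follows
#' `kappa(z) = kappa0 * L(Q; Q50(rho)) * exp(-(rho - rho*)^2 / (2 * sigma_rho^2))`
#' with `rho = sqrt(d^2 + z^2)` the 3D vessel-to-centre distance,
#' `Q50(rho) = Qc * exp(-rho / rho_c)` the flow at half-maximal response, and
#' `L` a logistic in log-flow (`L(0) = 0`, `L -> 1` for `Q >> Q50`). The
#' white-zone boundary of the slice at offset `z` is
#' `r(theta) = r0(z) * (1 - kappa(z) * exp(-dtheta^2 / (2 * sigma_theta^2)))`
#' plus i.i.d. radial vertex noise, where `r0(z) = b * sqrt(1 - (z/a)^2)`
#' and `dtheta` is the azimuthal offset from the vessel direction. The law is
#' generative, not biophysical: it is built so that cooling grows with flow,
#' peaks when the vessel sits near the ablation border (`rho* ~ 7.5` mm),
#' and vanishes without perfusion.
#'
#' @param av_distance_mm Antenna-vessel distance `d` in mm (> 0).
#' @param flow_ml_min Coolant flow `Q` in ml/min (>= 0).
#' @param seed Integer seed; mandatory, no global RNG state is consumed.
#' @param semi_axis_a_mm,semi_axis_b_mm Ellipsoid semi-axes (mm); defaults
#'   18 and 16 (a nominal 3.6 x 3.2 cm ablation).
#' @param notch_depth_max Maximal relative indentation depth `kappa0` in
#'   `[0, 1)`.
#' @param notch_azimuth_sigma_rad Azimuthal width of the notch (rad).
#' @param border_peak_mm,border_sigma_mm Centre `rho*` and width of the
#'   border-proximity peak (mm).
#' @param flow_midpoint_base_ml_min,flow_midpoint_decay_mm `Qc` and `rho_c`
#'   of the half-response flow `Q50(rho) = Qc * exp(-rho / rho_c)`.
#' @param flow_logistic_width Width of the logistic in `log(Q)`; smaller
#'   values switch the flow response on more sharply.
#' @param rz_margin_mm Radial margin of the red zone outside the white zone.
#' @param boundary_noise_sd_mm Radial vertex noise sd (mm).
#' @param size_jitter_sd Relative sd of a per-ablation isotropic scale
#'   factor applied to both semi-axes (replicate-to-replicate variability).
#' @param polygon_vertices_per_slice Vertices per contour (>= 16).
#' @param slice_spacing_mm Section interval (mm).
#' @param axial_extent_mm Sections are placed at `z = 0, +-spacing, ...`
#'   out to this extent, clipped to `|z| < a`.
#' @param min_traceable_radius_mm Sections whose noise-free white-zone
#'   radius falls below this value are not emitted: a contour of only a few
#'   millimetres at the stack poles cannot be reliably identified and traced
#'   on a photographed section, and serial-section studies accordingly
#'   record fewer slices per ablation than the nominal axial range allows.
#' @param vessel_outer_radius_mm,vessel_inner_radius_mm Vessel wall radii
#'   (mm); outer 2.5 / inner 1.5 mimic a 5.0 / 3.0 mm diameter glass tube.
#' @return An object of class `phantom_params`.
#' @seealso [generate_stack()], [simulate_study()]
#' @export
phantom_params <- function(av_distance_mm = 5,
                           flow_ml_min = 0,
                           seed,
                           semi_axis_a_mm = 18,
                           semi_axis_b_mm = 16,
                           notch_depth_max = 0.70,
                           notch_azimuth_sigma_rad = 0.45,
                           border_peak_mm = 7.5,
                           border_sigma_mm = 3.0,
                           flow_midpoint_base_ml_min = 20,
                           flow_midpoint_decay_mm = 4.0,
                           flow_logistic_width = 0.45,
                           rz_margin_mm = 3.0,
                           boundary_noise_sd_mm = 0.25,
                           size_jitter_sd = 0.02,
                           polygon_vertices_per_slice = 128L,
                           slice_spacing_mm = 2,
                           axial_extent_mm = 20,
                           min_traceable_radius_mm = 5,
                           vessel_outer_radius_mm = 2.5,
                           vessel_inner_radius_mm = 1.5) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop_parameter("`seed` is mandatory for phantom generation")
  }
  p <- structure(
    list(av_distance_mm = as.numeric(av_distance_mm),
         flow_ml_min = as.numeric(flow_ml_min),
         seed = as.integer(seed),
         semi_axis_a_mm = as.numeric(semi_axis_a_mm),
         semi_axis_b_mm = as.numeric(semi_axis_b_mm),
         notch_depth_max = as.numeric(notch_depth_max),
         notch_azimuth_sigma_rad = as.numeric(notch_azimuth_sigma_rad),
         border_peak_mm = as.numeric(border_peak_mm),
         border_sigma_mm = as.numeric(border_sigma_mm),
         flow_midpoint_base_ml_min = as.numeric(flow_midpoint_base_ml_min),
         flow_midpoint_decay_mm = as.numeric(flow_midpoint_decay_mm),
         flow_logistic_width = as.numeric(flow_logistic_width),
         rz_margin_mm = as.numeric(rz_margin_mm),
         boundary_noise_sd_mm = as.numeric(boundary_noise_sd_mm),
         size_jitter_sd = as.numeric(size_jitter_sd),
         polygon_vertices_per_slice = as.integer(polygon_vertices_per_slice),
         slice_spacing_mm = as.numeric(slice_spacing_mm),
         axial_extent_mm = as.numeric(axial_extent_mm),
         min_traceable_radius_mm = as.numeric(min_traceable_radius_mm),
         vessel_outer_radius_mm = as.numeric(vessel_outer_radius_mm),
         vessel_inner_radius_mm = as.numeric(vessel_inner_radius_mm)),
    class = "phantom_params")
  validate_phantom_params(p)
}

validate_phantom_params <- function(p) {
  if (!is.finite(p$notch_depth_max) || p$notch_depth_max < 0 ||
      p$notch_depth_max >= 1) {
    stop_parameter("`notch_depth_max` must lie in [0, 1)")
  }
  if (!is.finite(p$av_distance_mm) || p$av_distance_mm <= 0) {
    stop_parameter("`av_distance_mm` must be > 0")
  }
  if (!is.finite(p$flow_ml_min) || p$flow_ml_min < 0) {
    stop_parameter("`flow_ml_min` must be >= 0")
  }
  lengths <- c(p$semi_axis_a_mm, p$semi_axis_b_mm, p$border_peak_mm,
               p$border_sigma_mm, p$flow_midpoint_base_ml_min,
               p$flow_midpoint_decay_mm, p$flow_logistic_width,
               p$notch_azimuth_sigma_rad, p$slice_spacing_mm,
               p$axial_extent_mm, p$vessel_outer_radius_mm,
               p$vessel_inner_radius_mm)
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop_parameter("all phantom length/scale parameters must be > 0")
  }
  if (p$rz_margin_mm < 0 || p$boundary_noise_sd_mm < 0 ||
      p$size_jitter_sd < 0) {
    stop_parameter("noise, jitter and margin parameters must be >= 0")
  }
  if (!is.finite(p$min_traceable_radius_mm) || p$min_traceable_radius_mm < 0 ||
      p$min_traceable_radius_mm >= p$semi_axis_b_mm) {
    stop_parameter("`min_traceable_radius_mm` must lie in [0, semi_axis_b_mm)")
  }
  if (p$vessel_inner_radius_mm >= p$vessel_outer_radius_mm) {
    stop_parameter("vessel inner radius must be smaller than outer radius")
  }
  if (p$polygon_vertices_per_slice < 16L) {
    stop_parameter("`polygon_vertices_per_slice` must be >= 16")
  }
  p
}

# Logistic flow response in log-flow: L(0) = 0, L(Q50) = 1/2, L -> 1 for
# Q >> Q50. `width` is the logistic scale on the log(Q) axis.
logistic_flow <- function(flow, q50, width) {
  if (flow <= 0) return(rep(0, length(q50)))
  1 / (1 + (q50 / flow)^(1 / width))
}

# Indentation depth kappa(z) of the generative law, vectorised over z.
notch_kappa <- function(params, z) {
  rho <- sqrt(params$av_distance_mm^2 + z^2)
  q50 <- params$flow_midpoint_base_ml_min *
    exp(-rho / params$flow_midpoint_decay_mm)
  params$notch_depth_max *
    logistic_flow(params$flow_ml_min, q50, params$flow_logistic_width) *
    exp(-(rho - params$border_peak_mm)^2 / (2 * params$border_sigma_mm^2))
}

#' Generate one synthetic slice stack with analytic ground truth
#'
#' Draws a full serial-section stack for one ablation from the generative
#' law of [phantom_params()]: white-zone (and red-zone) contour polygons at
#' offsets `z = 0, +-spacing, ...` with `|z| < a`, star-shaped about the
#' antenna point at the in-plane origin, the vessel centred at `(d, 0)`.
#' Ground truth (half-ablation, idealized and cooling volumes; per-slice
#' cooling areas and types) is computed from the noise-free boundary law by
#' high-resolution numerical integration (0.1 mm axial / 4001-point angular
#' grid over the sectioned span), independently of the measurement pipeline.
#'
#' @param params A `phantom_params` object.
#' @param run_id,replicate Identifier metadata stamped on the slice rows.
#' @return A list of class `phantom_stack` with elements
#'   `slices` (a slice table tibble, WZ and RZ rows) and `truth` (a list:
#'   `half_ablation_volume_ml`, `idealized_volume_ml`, `cooling_volume_ml`,
#'   `scale_factor`, and a per-slice tibble `slice_truth`).
#' @examples
#' stack <- generate_stack(phantom_params(av_distance_mm = 5,
#'                                        flow_ml_min = 100, seed = 7))
#' stack$truth$cooling_volume_ml
#' @export
generate_stack <- function(params, run_id = "phantom", replicate = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  validate_phantom_params(params)
  withr::with_seed(params$seed, {
    scale <- if (params$size_jitter_sd > 0) {
      max(0.5, min(1.5, 1 + rnorm(1, 0, params$size_jitter_sd)))
    } else 1
    a <- params$semi_axis_a_mm * scale
    b <- params$semi_axis_b_mm * scale
    offsets <- seq(-params$axial_extent_mm, params$axial_extent_mm,
                   by = params$slice_spacing_mm)
    offsets <- offsets[abs(offsets) < a - 1e-9]
    # traceability cutoff: drop polar sections too small to outline reliably
    r0_all <- b * sqrt(1 - (offsets / a)^2)
    offsets <- offsets[r0_all >= params$min_traceable_radius_mm]
    if (length(offsets) < 2) {
      stop_parameter("phantom yields fewer than 2 slices; increase `axial_extent_mm` or `semi_axis_a_mm`")
    }
    m <- params$polygon_vertices_per_slice
    theta <- -pi + (seq_len(m) - 0.5) * 2 * pi / m  # CCW, no vertex at +-pi/2
    g <- exp(-theta^2 / (2 * params$notch_azimuth_sigma_rad^2))
    d <- params$av_distance_mm

    slice_rows <- purrr::map(offsets, function(z) {
      r0 <- b * sqrt(1 - (z / a)^2)
      kap <- notch_kappa(params, z)
      r <- r0 * (1 - kap * g)
      if (params$boundary_noise_sd_mm > 0) {
        r <- r + rnorm(m, 0, params$boundary_noise_sd_mm)
      }
      r <- pmax(r, 0.05)
      wz <- cbind(r * cos(theta), r * sin(theta))
      rz <- cbind((r + params$rz_margin_mm) * cos(theta),
                  (r + params$rz_margin_mm) * sin(theta))
      tibble(offset_mm = z, zone = c("WZ", "RZ"),
             polygon = list(wz, rz))
    })
  })
  slices <- dplyr::bind_rows(slice_rows)
  slices <- tibble(
    run_id = run_id,
    av_distance_mm = params$av_distance_mm,
    flow_ml_min = params$flow_ml_min,
    replicate = as.integer(replicate),
    offset_mm = slices$offset_mm,
    zone = slices$zone,
    polygon = slices$polygon,
    antenna_x = 0, antenna_y = 0,
    vessel_x = params$av_distance_mm, vessel_y = 0,
    vessel_outer_radius_mm = params$vessel_outer_radius_mm,
    scale_mm_per_unit = 1
  )
  truth <- phantom_truth(params, a, b, offsets)
  truth$scale_factor <- scale
  structure(list(slices = slices, truth = truth), class = "phantom_stack")
}

# High-resolution numerical ground truth of the noise-free phantom over the
# sectioned axial span (serial sectioning cannot see beyond the outermost
# slice, so truth and reconstruction describe the same region).
phantom_truth <- function(params, a, b, offsets,
                          n_theta = 4001L, axial_step_mm = NULL) {
  axial_step_mm <- axial_step_mm %||% (params$slice_spacing_mm / 20)
  zmax <- max(abs(offsets))
  z <- seq(-zmax, zmax, length.out = max(201L, 2L * ceiling(zmax / axial_step_mm) + 1L))
  theta <- seq(-pi / 2, pi / 2, length.out = n_theta)  # vessel half only
  g <- exp(-theta^2 / (2 * params$notch_azimuth_sigma_rad^2))
  r0 <- b * sqrt(pmax(0, 1 - (z / a)^2))
  kap <- notch_kappa(params, z)
  # boundary radius matrix: rows z, cols theta
  r <- outer(r0, rep(1, length(theta))) - outer(r0 * kap, g)
  half_area <- trapz_rows(r^2, theta) / 2
  ideal_area <- 0.5 * pi * r0^2
  half_vol <- trapz(z, half_area) / 1000
  ideal_vol <- trapz(z, ideal_area) / 1000

  slice_truth <- purrr::map_dfr(offsets, function(z1) {
    r01 <- b * sqrt(max(0, 1 - (z1 / a)^2))
    k1 <- notch_kappa(params, z1)
    rb <- r01 * (1 - k1 * g)
    ca <- (0.5 * pi * r01^2) - trapz(theta, rb^2) / 2
    f1 <- enclosure_truth(params, r01, k1)
    tibble(offset_mm = z1,
           rho_mm = sqrt(params$av_distance_mm^2 + z1^2),
           kappa = k1,
           true_cooling_area_mm2 = max(0, ca),
           true_enclosure_fraction = f1,
           true_cooling_type = classify_cooling(min(1, max(0, k1)), f1))
  })
  list(half_ablation_volume_ml = half_vol,
       idealized_volume_ml = ideal_vol,
       cooling_volume_ml = max(0, ideal_vol - half_vol),
       slice_truth = slice_truth)
}

# Enclosure fraction of the vessel disc against the analytic boundary:
# decided exactly (0/1) when every sampled point clears the boundary with a
# margin, sampled on a dense polar grid otherwise.
enclosure_truth <- function(params, r0, kappa) {
  d <- params$av_distance_mm
  rv <- params$vessel_outer_radius_mm
  rr <- rv * sqrt(seq(0.5, 39.5) / 40)
  aa <- seq(0, 2 * pi, length.out = 145)[-145]
  px <- d + as.vector(outer(rr, cos(aa)))
  py <- as.vector(outer(rr, sin(aa)))
  ang <- atan2(py, px)
  rad <- sqrt(px^2 + py^2)
  rb <- r0 * (1 - kappa * exp(-ang^2 / (2 * params$notch_azimuth_sigma_rad^2)))
  inside <- rad <= rb
  if (all(inside)) 1 else if (!any(inside)) 0 else mean(inside)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

trapz_rows <- function(m, x) {
  w <- diff(x)
  as.vector((m[, -1, drop = FALSE] + m[, -ncol(m), drop = FALSE]) %*% (w / 2))
}

#' Draw coolant temperature rises
#'
#' Simulates the end-to-end temperature increase of the coolant over one
#' ablation, as measured for the high-flow series (>= 100 ml/min) of the
#' study design: truncated-normal draws (default mean 0.6 K, sd 0.1 K,
#' truncated at 0).
#'
#' @param flow_ml_min Flow rate; must be >= 100 ml/min (the temperature rise
#'   is only measured for the high-flow series).
#' @param n Number of draws (>= 1).
#' @param seed Mandatory integer seed.
#' @param mean_K,sd_K Mean and sd of the untruncated normal (K).
#' @return A numeric vector of `n` temperature rises (K, >= 0).
#' @examples
#' generate_delta_t(500, n = 6, seed = 3)
#' @export
generate_delta_t <- function(flow_ml_min, n, seed, mean_K = 0.6, sd_K = 0.1) {
  if (!is.finite(flow_ml_min) || flow_ml_min < 100) {
    stop_parameter("`flow_ml_min` must be >= 100 (delta-T is only measured for high-flow series)")
  }
  if (missing(seed) || !is.finite(seed)) stop_parameter("`seed` is mandatory")
  if (!is.finite(n) || n < 1) stop_parameter("`n` must be >= 1")
  if (sd_K < 0) stop_parameter("`sd_K` must be >= 0")
  withr::with_seed(as.integer(seed), {
    draws <- rnorm(n, mean_K, sd_K)
    while (any(draws < 0)) {
      bad <- draws < 0
      draws[bad] <- rnorm(sum(bad), mean_K, sd_K)
    }
    draws
  })
}

#' Simulate a full factorial ablation study
#'
#' Generates one phantom stack per planned run of a [study_design()], with
#' per-run seeds derived deterministically from `seed`.
#'
#' @param design A `study_design`.
#' @param seed Integer master seed.
#' @param params Named list of [phantom_params()] overrides applied to every
#'   run (everything except `av_distance_mm`, `flow_ml_min`,
#'   `slice_spacing_mm` and `seed`, which come from the design and run).
#' @return A list of class `mwa_study`: `slices` (the pooled slice table),
#'   `truth` (per-run tibble of true volumes), `design`, `seed`.
#' @examples
#' study <- simulate_study(study_design(c(2.5, 5), c(0, 100), replicates = 2),
#'                         seed = 1)
#' study$truth
#' @export
simulate_study <- function(design = study_design(), seed, params = list()) {
  if (missing(seed) || !is.finite(seed)) stop_parameter("`seed` is mandatory")
  runs <- enumerate_runs(design)
  run_seeds <- withr::with_seed(as.integer(seed),
                                sample.int(2147483646L, nrow(runs)))
  fixed <- c("av_distance_mm", "flow_ml_min", "slice_spacing_mm", "seed")
  if (any(names(params) %in% fixed)) {
    stop_parameter(paste0("`params` may not override: ",
                          paste(intersect(names(params), fixed), collapse = ", ")))
  }
  stacks <- purrr::pmap(
    list(runs$run_id, runs$av_distance_mm, runs$flow_ml_min, runs$replicate,
         run_seeds),
    function(id, d, q, rep_i, s) {
      pp <- do.call(phantom_params, c(
        list(av_distance_mm = d, flow_ml_min = q, seed = s,
             slice_spacing_mm = design$slice_spacing_mm), params))
      generate_stack(pp, run_id = id, replicate = rep_i)
    })
  slices <- dplyr::bind_rows(purrr::map(stacks, "slices"))
  truth <- dplyr::bind_cols(
    runs,
    purrr::map_dfr(stacks, function(s) {
      tibble(true_half_volume_ml = s$truth$half_ablation_volume_ml,
             true_idealized_volume_ml = s$truth$idealized_volume_ml,
             true_cooling_volume_ml = s$truth$cooling_volume_ml,
             scale_factor = s$truth$scale_factor)
    }))
  structure(list(slices = slices, truth = truth, design = design,
                 seed = as.integer(seed)),
            class = "mwa_study")
}

#' @export
print.mwa_study <- function(x, ...) {
  cat("<mwa_study>\n")
  cat(sprintf("  %d runs, %d slice contours (seed %d)\n",
              nrow(x$truth), nrow(x$slices), x$seed))
  print(x$design)
  invisible(x)
}
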