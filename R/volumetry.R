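#' Truncated-cone (trapezoidal) volume from serial slice areas
#'
#' Reconstructs a volume from ordered cross-sectional areas measured every
#' `spacing_mm` along the antenna axis, summing truncated-cone elements
#' `(A_i + A_{i+1}) / 2 * spacing` between consecutive slices.
#'
#' @param areas_mm2 Ordered slice areas in mm^2 (>= 2 values, all >= 0).
#' @param spacing_mm Slice spacing in mm (> 0).
#' @return Volume in ml.
#' @examples
#' frustum_volume(rep(50, 11), 2) # 1 ml
#' @export
frustum_volume <- function(areas_mm2, spacing_mm = 2) {
  a <- as.numeric(areas_mm2)
  if (length(a) < 2) {
    stop_mwacool("need at least 2 slice areas to reconstruct a volume",
                 "mwacool_measurement_error")
  }
  if (any(!is.finite(a)) || any(a < 0)) {
    stop_data("slice areas must be finite and >= 0")
  }
  if (!is.finite(spacing_mm) || spacing_mm <= 0) {
    stop_parameter("`spacing_mm` must be > 0")
  }
  n <- length(a)
  sum((a[-n] + a[-1]) / 2 * spacing_mm) / 1000
}

#' Idealized (uncooled) half-ablation area for a slice
#'
#' Area of the half-disc of radius `r_max_mm`: the cross section an
#' uncooled, rotationally symmetric ablation would show on the vessel side,
#' reconstructed from the maximum radius actually attained in the slice.
#'
#' @param r_max_mm Maximum ablation radius of the slice (mm, >= 0).
#' @return Half-disc area in mm^2 (`pi * r_max^2 / 2`).
#' @examples
#' idealized_half_area(10) # 157.08
#' @export
idealized_half_area <- function(r_max_mm) {
  if (any(!is.finite(r_max_mm)) || any(r_max_mm < 0)) {
    stop_data("`r_max_mm` must be finite and >= 0")
  }
  0.5 * pi * r_max_mm^2
}

#' Per-slice cooling area
#'
#' Difference between the idealized half-ablation area and the measured
#' vessel-half area; the in-plane footprint of the heat-sink deformation.
#' Small negative differences (boundary noise pushing the traced contour
#' slightly beyond the idealized half-disc) clamp to zero; a clamp larger
#' than `1e-6 * idealized` is reported with a warning.
#'
#' @param half_area_mm2 Measured vessel-half white-zone area (mm^2).
#' @param idealized_half_area_mm2 Idealized half-disc area (mm^2).
#' @return Cooling area in mm^2 (>= 0).
#' @export
cooling_area <- function(half_area_mm2, idealized_half_area_mm2) {
  if (any(!is.finite(half_area_mm2)) || any(!is.finite(idealized_half_area_mm2))) {
    stop_data("cooling_area() needs finite half and idealized areas")
  }
  diff <- idealized_half_area_mm2 - half_area_mm2
  clamped <- diff < 0
  if (any(clamped & -diff > 1e-6 * idealized_half_area_mm2)) {
    warn(sprintf(
      "clamping %d negative cooling area(s) to 0 (largest excess %.3g mm^2)",
      sum(clamped), max(-diff[clamped])))
  }
  pmax(0, diff)
}

#' Cooling volume as a percentage of the ablation volume
#'
#' The "cooling portion" of a run: `100 * cooling / ablation`, rounded to
#' the nearest integer percent for tabulation (set `rounded = FALSE` for
#' full precision). Undefined for a zero ablation volume, in which case
#' `NA` is returned with a warning.
#'
#' @param cooling_volume_ml Cooling volume (ml, >= 0).
#' @param ablation_volume_ml Ablation volume (ml, > 0).
#' @param rounded Round to integer percent (default `TRUE`).
#' @return Percentage (vectorised).
#' @examples
#' cooling_portion(1.8, 5.4) # 33
#' @export
cooling_portion <- function(cooling_volume_ml, ablation_volume_ml,
                            rounded = TRUE) {
  if (any(!is.finite(cooling_volume_ml)) || any(cooling_volume_ml < 0)) {
    stop_data("`cooling_volume_ml` must be finite and >= 0")
  }
  undefined <- !is.finite(ablation_volume_ml) | ablation_volume_ml <= 0
  if (any(undefined)) {
    warn("cooling portion undefined for non-positive ablation volume; returning NA")
  }
  pct <- ifelse(undefined, NA_real_,
                100 * cooling_volume_ml / ablation_volume_ml)
  if (rounded) round(pct) else pct
}

#' Per-run volume reconstruction
#'
#' Aggregates per-slice measurements (see [measure_slices()]) into one report
#' per run: the vessel-half ablation volume, the idealized volume, their
#' difference (the cooling volume), and the cooling portion. Both volumes use
#' the truncated-cone formula over the same ordered slices, so the additivity
#' `idealized = ablation + cooling` holds exactly.
#'
#' @param measurements A measurement tibble from [measure_slices()].
#' @param spacing_mm Slice spacing in mm; consecutive offsets within a run
#'   must differ by this value within 0.01 mm.
#' @return A tibble of class `stack_reports`, one row per run:
#'   `run_id`, `av_distance_mm`, `flow_ml_min`, `replicate`, `n_slices`,
#'   `ablation_volume_ml`, `idealized_volume_ml`, `cooling_volume_ml`,
#'   `cooling_portion_pct` (full precision).
#' @examples
#' study <- simulate_study(study_design(5, c(0, 500), replicates = 1), seed = 1)
#' stack_reports(measure_slices(study$slices))
#' @export
stack_reports <- function(measurements, spacing_mm = 2) {
  required <- c("run_id", "av_distance_mm", "flow_ml_min", "replicate",
                "offset_mm", "half_area_mm2", "idealized_half_area_mm2")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop_data(paste0("measurement table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  out <- measurements |>
    dplyr::group_by(.data$run_id, .data$av_distance_mm, .data$flow_ml_min,
                    .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$offset_mm)
      check_uniform_spacing(df$offset_mm, key$run_id, spacing_mm)
      tibble(
        n_slices = nrow(df),
        ablation_volume_ml = frustum_volume(df$half_area_mm2, spacing_mm),
        idealized_volume_ml = frustum_volume(df$idealized_half_area_mm2,
                                             spacing_mm)
      )
    }) |>
    dplyr::ungroup()
  out$cooling_volume_ml <- pmax(0, out$idealized_volume_ml - out$ablation_volume_ml)
  out$cooling_portion_pct <- cooling_portion(out$cooling_volume_ml,
                                             out$ablation_volume_ml,
                                             rounded = FALSE)
  structure(dplyr::arrange(out, .data$av_distance_mm, .data$flow_ml_min,
                           .data$replicate),
            class = c("stack_reports", class(out)))
}

check_uniform_spacing <- function(offsets, run_id, spacing_mm, tol = 0.01) {
  d <- diff(sort(offsets))
  if (length(d) == 0) {
    stop_data(sprintf("run %s has a single slice; cannot reconstruct a volume",
                      run_id))
  }
  if (any(abs(d - spacing_mm) > tol)) {
    stop_data(sprintf(
      "run %s: slice offsets are not uniformly spaced at %g mm (offsets %s)",
      run_id, spacing_mm, paste(sort(offsets), collapse = ", ")))
  }
  invisible(TRUE)
}
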