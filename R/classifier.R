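#' Semi-quantitative cooling classification (Types 0-III)
#'
#' Grades the vessel-induced deformation of a slice on the four-level scheme
#' used for visual scoring of ablation cross sections:
#'
#' * **Type 0 (none):** no relevant indentation.
#' * **Type I (minor):** the contour is slightly indented towards the vessel.
#' * **Type II (moderate):** pronounced indentation with the vessel still
#'   partly enclosed by the ablation.
#' * **Type III (major):** pronounced indentation and the vessel lies
#'   entirely outside the ablation.
#'
#' The visual scheme is operationalized with two thresholds on the
#' indentation ratio `iota = 1 - r(vessel azimuth) / r_max`: `iota <
#' tau_minor` is Type 0; `tau_minor <= iota < tau_moderate` is Type I;
#' `iota >= tau_moderate` is Type III when the enclosure fraction is 0,
#' Type II when it is strictly between 0 and 1, and Type I when the vessel
#' is still fully enclosed (a deep but vessel-distant indentation).
#' "Outside" and "fully enclosed" are decided at a relative tolerance of
#' 1e-6 on the enclosure fraction.
#'
#' @param indentation_ratio Indentation ratio(s) in `[0, 1]`.
#' @param enclosure_fraction Vessel enclosure fraction(s) in `[0, 1]`, see
#'   [vessel_enclosure_fraction()].
#' @param tau_minor,tau_moderate Thresholds with
#'   `0 < tau_minor < tau_moderate < 1`; defaults 0.05 and 0.20.
#' @return Integer cooling type(s) 0-3.
#' @examples
#' classify_cooling(0.5, 0)   # 3: vessel outside the ablation
#' classify_cooling(0.3, 0.5) # 2: vessel partly enclosed
#' @export
classify_cooling <- function(indentation_ratio, enclosure_fraction,
                             tau_minor = 0.05, tau_moderate = 0.20) {
  if (!(tau_minor > 0 && tau_minor < tau_moderate && tau_moderate < 1)) {
    stop_parameter("need 0 < tau_minor < tau_moderate < 1")
  }
  iota <- as.numeric(indentation_ratio)
  f <- as.numeric(enclosure_fraction)
  if (any(!is.finite(iota)) || any(iota < 0 | iota > 1)) {
    stop_data("`indentation_ratio` must lie in [0, 1]")
  }
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop_data("`enclosure_fraction` must lie in [0, 1]")
  }
  eps <- 1e-6
  outside <- f <= eps
  full <- f >= 1 - eps
  type <- integer(length(iota))
  deep <- iota >= tau_moderate
  type[deep & outside] <- 3L
  type[deep & !outside & !full] <- 2L
  type[deep & full] <- 1L
  minor <- !deep & iota >= tau_minor
  type[minor] <- 1L
  type
}

#' Label cooling types
#'
#' @param type Integer cooling type(s) 0-3.
#' @return An ordered factor with levels `none < minor < moderate < major`.
#' @export
cooling_type_label <- function(type) {
  if (any(!type %in% 0:3)) stop_data("cooling types must be integers 0-3")
  factor(c("none", "minor", "moderate", "major")[type + 1],
         levels = c("none", "minor", "moderate", "major"), ordered = TRUE)
}

#' Cooling-type profile against vessel-to-centre distance
#'
#' Bins measured slices by the 3D distance `rho = sqrt(d^2 + z^2)` between
#' the vessel and the ablation centre point (the vessel runs parallel to the
#' antenna at in-plane distance `d`; `z` is the slice offset) and averages
#' the cooling type per bin, pooled or per A-V distance group.
#'
#' @param measurements A measurement tibble from [measure_slices()] (needs
#'   `rho_mm` and `cooling_type`; `av_distance_mm` when `by_distance`).
#' @param bin_width_mm Bin width in mm (default 1).
#' @param by_distance Profile per A-V distance group instead of pooled.
#' @return A tibble of class `cooling_profile` with columns `rho_mm` (bin
#'   centre), `mean_type`, `n` (and `av_distance_mm` when grouped).
#' @examples
#' study <- simulate_study(study_design(5, c(0, 500), replicates = 1), seed = 1)
#' type_profile(measure_slices(study$slices))
#' @export
type_profile <- function(measurements, bin_width_mm = 1,
                         by_distance = FALSE) {
  if (nrow(measurements) == 0) stop_data("no slices to profile")
  if (!all(c("rho_mm", "cooling_type") %in% names(measurements))) {
    stop_data("measurements need `rho_mm` and `cooling_type` columns")
  }
  if (!is.finite(bin_width_mm) || bin_width_mm <= 0) {
    stop_parameter("`bin_width_mm` must be > 0")
  }
  df <- measurements
  df$rho_bin <- (floor(df$rho_mm / bin_width_mm) + 0.5) * bin_width_mm
  groups <- if (by_distance) c("av_distance_mm", "rho_bin") else "rho_bin"
  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(mean_type = mean(.data$cooling_type),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::rename(rho_mm = "rho_bin") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(
      if (by_distance) c("av_distance_mm", "rho_mm") else "rho_mm")))
  structure(out, class = c("cooling_profile", class(out)),
            bin_width_mm = bin_width_mm)
}
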