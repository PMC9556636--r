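#' Define the factorial ablation study design
#'
#' Holds the full factorial configuration of an ex vivo vascular-cooling
#' experiment: antenna-vessel (A-V) distances, coolant flow rates, replicates
#' per cell, generator power and duration, serial-section spacing, and the
#' nominal (uncooled) ablation size. Defaults encode a 3 x 7 x 6 design:
#' A-V distances 2.5/5.0/10.0 mm, flows 0-500 ml/min, n = 6, 100 W for 5 min,
#' 2 mm sections, 3.6 x 3.2 cm nominal ablation.
#'
#' @param av_distances_mm Antenna-vessel distances in mm, all > 0.
#' @param flow_rates_ml_min Coolant flow rates in ml/min, non-negative and
#'   strictly increasing.
#' @param replicates Ablations per design cell (>= 1).
#' @param power_W Generator power in W (> 0).
#' @param duration_s Ablation duration in s (> 0).
#' @param slice_spacing_mm Serial-section interval in mm (> 0).
#' @param expected_ablation_mm Length and width (mm) of the nominal ablation
#'   the manufacturer predicts without vascular cooling.
#'
#' @return An object of class `study_design` (a validated list).
#' @seealso [enumerate_runs()], [simulate_study()]
#' @examples
#' design <- study_design()
#' nrow(enumerate_runs(design)) # 126 planned ablations
#' @export
study_design <- function(av_distances_mm = c(2.5, 5.0, 10.0),
                         flow_rates_ml_min = c(0, 1, 2, 5, 10, 100, 500),
                         replicates = 6L,
                         power_W = 100,
                         duration_s = 300,
                         slice_spacing_mm = 2,
                         expected_ablation_mm = c(length = 36, width = 32)) {
  design <- structure(
    list(
      av_distances_mm = as.numeric(av_distances_mm),
      flow_rates_ml_min = as.numeric(flow_rates_ml_min),
      replicates = as.integer(replicates),
      power_W = as.numeric(power_W),
      duration_s = as.numeric(duration_s),
      slice_spacing_mm = as.numeric(slice_spacing_mm),
      expected_ablation_mm = as.numeric(expected_ablation_mm)
    ),
    class = "study_design"
  )
  validate_study_design(design)
}

validate_study_design <- function(design) {
  with(design, {
    if (length(av_distances_mm) < 1 || any(!is.finite(av_distances_mm)) ||
        any(av_distances_mm <= 0)) {
      stop_config("invalid design: all `av_distances_mm` must be finite and > 0")
    }
    if (length(flow_rates_ml_min) < 1 || any(!is.finite(flow_rates_ml_min)) ||
        any(flow_rates_ml_min < 0)) {
      stop_config("invalid design: all `flow_rates_ml_min` must be finite and >= 0")
    }
    if (is.unsorted(flow_rates_ml_min, strictly = TRUE)) {
      stop_config("invalid design: `flow_rates_ml_min` must be strictly increasing")
    }
    if (is.na(replicates) || replicates < 1L) {
      stop_config("invalid design: `replicates` must be >= 1")
    }
    if (!is.finite(power_W) || power_W <= 0) {
      stop_config("invalid design: `power_W` must be > 0")
    }
    if (!is.finite(duration_s) || duration_s <= 0) {
      stop_config("invalid design: `duration_s` must be > 0")
    }
    if (!is.finite(slice_spacing_mm) || slice_spacing_mm <= 0) {
      stop_config("invalid design: `slice_spacing_mm` must be > 0")
    }
  })
  design
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat("  A-V distances (mm): ", paste(x$av_distances_mm, collapse = ", "), "\n")
  cat("  flow rates (ml/min):", paste(x$flow_rates_ml_min, collapse = ", "), "\n")
  cat("  replicates per cell:", x$replicates, "\n")
  cat(sprintf("  power/duration:      %g W for %g s\n", x$power_W, x$duration_s))
  cat(sprintf("  slice spacing:       %g mm\n", x$slice_spacing_mm))
  cat(sprintf("  planned runs:        %d\n", nrow(enumerate_runs(x))))
  invisible(x)
}

#' Enumerate the planned ablation runs of a design
#'
#' Expands a [study_design()] into its planned runs, one per
#' (distance, flow, replicate) combination, in deterministic lexicographic
#' order by distance, then flow, then replicate.
#'
#' @param design A `study_design` object.
#' @return A tibble with columns `run_id`, `av_distance_mm`, `flow_ml_min`,
#'   `replicate`; exactly `length(distances) * length(flows) * replicates`
#'   rows.
#' @examples
#' enumerate_runs(study_design(2.5, c(0, 100), replicates = 2))
#' @export
enumerate_runs <- function(design) {
  if (!inherits(design, "study_design")) {
    stop_config("`design` must be a `study_design` object")
  }
  validate_study_design(design)
  runs <- expand.grid(
    replicate = seq_len(design$replicates),
    flow_ml_min = design$flow_rates_ml_min,
    av_distance_mm = design$av_distances_mm,
    KEEP.OUT.ATTRS = FALSE
  )
  runs <- as_tibble(runs[, c("av_distance_mm", "flow_ml_min", "replicate")])
  runs <- dplyr::arrange(runs, .data$av_distance_mm, .data$flow_ml_min,
                         .data$replicate)
  runs$run_id <- sprintf("d%05.1f_q%05.1f_r%02d", runs$av_distance_mm,
                         runs$flow_ml_min, runs$replicate)
  runs[, c("run_id", "av_distance_mm", "flow_ml_min", "replicate")]
}

#' Read a study design from a JSON configuration file
#'
#' The JSON keys mirror the arguments of [study_design()]; missing keys fall
#' back to the defaults.
#'
#' @param path Path to a JSON file.
#' @return A `study_design` object.
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop_load(paste0("design config not found: ", path))
  cfg <- jsonlite::fromJSON(path)
  known <- names(formals(study_design))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    stop_config(paste0("unknown design config key(s): ",
                       paste(extra, collapse = ", ")))
  }
  do.call(study_design, cfg)
}
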