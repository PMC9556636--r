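#' @import ggplot2
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the slice contours of one or more runs
#'
#' Draws the traced white-zone (and optionally red-zone) contours of a slice
#' table faceted by slice offset, with the antenna point and the vessel
#' cross section overlaid.
#'
#' @param slices A slice table tibble (see [measure_slices()] for columns).
#' @param run Run id(s) to draw; default the first run in the table.
#' @param zones Zones to draw, subset of `c("WZ", "RZ")`.
#' @return A ggplot object.
#' @export
plot_slices <- function(slices, run = NULL, zones = "WZ") {
  run <- run %||% slices$run_id[1]
  df <- dplyr::filter(slices, .data$run_id %in% run, .data$zone %in% zones)
  if (nrow(df) == 0) stop_data("no slices matching the requested run/zones")
  poly_df <- purrr::pmap_dfr(
    list(df$polygon, df$run_id, df$offset_mm, df$zone),
    function(p, id, z, zone) {
      p <- as_polygon(p, check_simple = FALSE)
      tibble(x = p[, 1], y = p[, 2], run_id = id, offset_mm = z, zone = zone)
    })
  vessel <- df[!duplicated(df$run_id), ]
  circle <- purrr::pmap_dfr(
    list(vessel$run_id, vessel$vessel_x, vessel$vessel_y,
         vessel$vessel_outer_radius_mm),
    function(id, vx, vy, vr) {
      th <- seq(0, 2 * pi, length.out = 90)
      tibble(x = vx + vr * cos(th), y = vy + vr * sin(th), run_id = id)
    })
  ggplot(poly_df, aes(x = .data$x, y = .data$y)) +
    geom_polygon(aes(group = .data$zone, colour = .data$zone), fill = NA) +
    geom_path(data = circle, colour = "steelblue", linetype = 2) +
    geom_point(data = vessel, aes(x = .data$antenna_x, y = .data$antenna_y),
               shape = 3) +
    facet_wrap(~offset_mm, labeller = label_both) +
    coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", colour = NULL,
         title = paste("Slice contours:", paste(run, collapse = ", "))) +
    theme_minimal()
}

#' @rdname plot_slices
#' @param object A `phantom_stack` from [generate_stack()].
#' @param ... Passed on to [plot_slices()].
#' @method autoplot phantom_stack
#' @export
autoplot.phantom_stack <- function(object, ...) {
  plot_slices(object$slices, ...)
}

#' Plot a cooling-type profile
#'
#' Binned mean cooling type against the vessel-to-ablation-centre distance,
#' with a LOESS curve (see [loess_fit()]) overlaid per group.
#'
#' @param object A `cooling_profile` from [type_profile()].
#' @param span LOESS span for the overlay (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cooling_profile
#' @export
autoplot.cooling_profile <- function(object, span = 0.5, ...) {
  grouped <- "av_distance_mm" %in% names(object)
  df <- as_tibble(object)
  smooth <- if (grouped) {
    df |>
      dplyr::group_by(.data$av_distance_mm) |>
      dplyr::group_modify(function(g, key) {
        if (nrow(g) < 4) return(tibble(x = numeric(), y = numeric()))
        tidy(loess_fit(g$rho_mm, g$mean_type, span = span))
      }) |>
      dplyr::ungroup()
  } else {
    tidy(loess_fit(df$rho_mm, df$mean_type, span = span))
  }
  p <- ggplot(df, aes(x = .data$rho_mm, y = .data$mean_type)) +
    geom_point(aes(size = .data$n), alpha = 0.6) +
    scale_size_area(max_size = 4) +
    labs(x = "vessel-to-ablation-centre distance rho (mm)",
         y = "mean cooling type (0-3)", size = "slices") +
    ylim(0, 3) +
    theme_minimal()
  if (grouped) {
    p + geom_line(data = smooth, aes(x = .data$x, y = .data$y),
                  linetype = 2) +
      facet_wrap(~av_distance_mm, labeller = label_both)
  } else {
    p + geom_line(data = smooth, aes(x = .data$x, y = .data$y),
                  linetype = 2, colour = "firebrick")
  }
}

#' Plot per-run volumes by flow rate
#'
#' Ablation and cooling volumes of a report table as boxplots per flow rate,
#' faceted by A-V distance.
#'
#' @param object A `stack_reports` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stack_reports
#' @export
autoplot.stack_reports <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::select("av_distance_mm", "flow_ml_min", "ablation_volume_ml",
                  "cooling_volume_ml") |>
    tidyr_pivot()
  ggplot(df, aes(x = factor(.data$flow_ml_min), y = .data$volume_ml,
                 fill = .data$quantity)) +
    geom_boxplot(outlier.size = 0.8) +
    facet_wrap(~av_distance_mm, labeller = label_both) +
    labs(x = "flow rate (ml/min)", y = "volume (ml)", fill = NULL) +
    theme_minimal()
}

# minimal long-format reshape; avoids importing tidyr for one call
tidyr_pivot <- function(df) {
  dplyr::bind_rows(
    tibble(av_distance_mm = df$av_distance_mm,
           flow_ml_min = df$flow_ml_min,
           quantity = "ablation", volume_ml = df$ablation_volume_ml),
    tibble(av_distance_mm = df$av_distance_mm,
           flow_ml_min = df$flow_ml_min,
           quantity = "cooling", volume_ml = df$cooling_volume_ml)
  )
}

#' @rdname autoplot.cooling_profile
#' @method autoplot loess_profile
#' @export
autoplot.loess_profile <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$x, y = .data$y)) +
    geom_line() +
    labs(x = "x", y = "fitted") +
    theme_minimal()
}
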