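#' Per-slice polygon planimetry
#'
#' The planimetry layer measures each 2 mm ablation cross section from its
#' traced white-zone contour: area by the shoelace rule, maximum radius from
#' the antenna point, clipping to the vessel-containing half-plane, the
#' boundary radius along an arbitrary azimuth, and the fraction of the vessel
#' lumen enclosed by the ablation. Coordinates are in mm with the antenna at
#' the in-plane origin and the vessel on the +x axis by convention; polygons
#' are ordered vertex matrices (two columns, last vertex not repeated).
#'
#' @name planimetry
NULL

# Coerce and validate a polygon: n x 2 numeric matrix, >= 3 vertices, finite,
# and (optionally) simple. Star-shapedness about the vertex-centroid is used
# as a cheap sufficient certificate of simplicity; only non-star polygons pay
# for the quadratic segment-intersection test.
as_polygon <- function(polygon, check_simple = TRUE) {
  p <- polygon
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, p)
  if (!is.matrix(p) || ncol(p) != 2 || !is.numeric(p)) {
    stop_geometry("polygon must be an n x 2 numeric matrix of vertices")
  }
  # drop a repeated closing vertex
  n <- nrow(p)
  if (n >= 2 && all(p[1, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3) stop_geometry("polygon needs at least 3 vertices")
  if (any(!is.finite(p))) stop_geometry("polygon has non-finite coordinates")
  if (check_simple && !is_star_shaped_about(p, colMeans(p)) &&
      !is_simple_polygon(p)) {
    stop_geometry("polygon is self-intersecting")
  }
  unname(p)
}

# Single-valued azimuth about `origin`: one monotone wrap of the angle.
is_star_shaped_about <- function(p, origin) {
  th <- atan2(p[, 2] - origin[2], p[, 1] - origin[1])
  d <- diff(th)
  d <- ifelse(d <= -pi, d + 2 * pi, ifelse(d > pi, d - 2 * pi, d))
  wrap <- (atan2(sin(th[1] - th[length(th)]), cos(th[1] - th[length(th)])))
  total <- sum(d) + wrap
  (all(d > 0) || all(d < 0)) && abs(abs(total) - 2 * pi) < 1e-6
}

# O(n^2) proper-intersection test between non-adjacent edges (vectorised).
is_simple_polygon <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  ij <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  adjacent <- ij[, 2] - ij[, 1] == 1 | (ij[, 1] == 1 & ij[, 2] == n)
  ij <- ij[!adjacent, , drop = FALSE]
  if (nrow(ij) == 0) return(TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  d1 <- cross2(b[i, ] - a[i, ], a[j, ] - a[i, ])
  d2 <- cross2(b[i, ] - a[i, ], b[j, ] - a[i, ])
  d3 <- cross2(b[j, ] - a[j, ], a[i, ] - a[j, ])
  d4 <- cross2(b[j, ] - a[j, ], b[i, ] - a[j, ])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(u, v) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 2)
  if (is.null(dim(v))) v <- matrix(v, ncol = 2)
  u[, 1] * v[, 2] - u[, 2] * v[, 1]
}

#' Polygon area by the shoelace rule
#'
#' @param polygon An n x 2 vertex matrix (mm), implicitly closed. Orientation
#'   does not matter; the absolute area is returned.
#' @param check_simple Validate that the polygon is simple (default `TRUE`);
#'   internal callers that have already validated can skip the check.
#' @return Area in mm^2.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))) # 6
#' @export
polygon_area <- function(polygon, check_simple = TRUE) {
  p <- as_polygon(polygon, check_simple = check_simple)
  n <- nrow(p)
  x <- p[, 1]; y <- p[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  abs(sum(x * yn - xn * y)) / 2
}

# Crossing-number point-in-polygon; boundary points count as inside.
point_in_polygon <- function(point, p) {
  x <- point[1]; y <- point[2]
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- p[c(2:n, 1), 1]; y2 <- p[c(2:n, 1), 2]
  # on-boundary test
  d <- abs((x2 - x1) * (y - y1) - (y2 - y1) * (x - x1))
  len2 <- (x2 - x1)^2 + (y2 - y1)^2
  t <- ((x - x1) * (x2 - x1) + (y - y1) * (y2 - y1)) / pmax(len2, 1e-300)
  on <- d^2 <= 1e-18 * pmax(len2, 1) & t >= 0 & t <= 1
  if (any(on)) return(TRUE)
  crosses <- ((y1 > y) != (y2 > y)) &
    (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
  sum(crosses) %% 2 == 1
}

#' Maximum boundary radius from a reference point
#'
#' Largest Euclidean distance from `origin` (normally the antenna point) to
#' the polygon boundary. For straight-edged polygons the maximum is attained
#' at a vertex.
#'
#' @param polygon An n x 2 vertex matrix (mm).
#' @param origin Length-2 reference point; must lie inside the polygon.
#' @return Maximum radius in mm.
#' @examples
#' max_radius(rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1)), c(0, 0)) # sqrt(2)
#' @export
max_radius <- function(polygon, origin = c(0, 0)) {
  p <- as_polygon(polygon)
  if (!point_in_polygon(origin, p)) {
    stop_geometry("`origin` lies outside the polygon")
  }
  sqrt(max((p[, 1] - origin[1])^2 + (p[, 2] - origin[2])^2))
}

#' Clip an ablation contour to its vessel-containing half
#'
#' Clips the polygon to the closed half-plane bounded by the line through
#' `antenna_point` perpendicular to the antenna-to-vessel direction, keeping
#' the side that contains the vessel. Cooling effects concentrate around the
#' vessel, so only this half enters the quantitative analysis; points exactly
#' on the dividing line belong to the vessel side.
#'
#' @param polygon An n x 2 vertex matrix (mm).
#' @param antenna_point In-plane antenna coordinates (mm).
#' @param vessel_centre In-plane vessel-centre coordinates (mm); must differ
#'   from `antenna_point`.
#' @return The clipped polygon as a vertex matrix.
#' @examples
#' sq <- rbind(c(2, 2), c(-2, 2), c(-2, -2), c(2, -2))
#' polygon_area(vessel_half(sq, c(0, 0), c(1, 0))) # 8: the x >= 0 half
#' @export
vessel_half <- function(polygon, antenna_point = c(0, 0),
                        vessel_centre = c(1, 0)) {
  p <- as_polygon(polygon)
  u <- vessel_centre - antenna_point
  nu <- sqrt(sum(u^2))
  if (!is.finite(nu) || nu < 1e-12) {
    stop_parameter("`vessel_centre` must differ from `antenna_point`")
  }
  u <- u / nu
  sdist <- (p[, 1] - antenna_point[1]) * u[1] +
    (p[, 2] - antenna_point[2]) * u[2]
  n <- nrow(p)
  out <- matrix(NA_real_, 2 * n, 2)
  k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- sdist[i]; sj <- sdist[j]
    if (si >= 0) {
      k <- k + 1; out[k, ] <- p[i, ]
    }
    if ((si >= 0) != (sj >= 0)) {
      t <- si / (si - sj)
      k <- k + 1; out[k, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  out <- out[seq_len(k), , drop = FALSE]
  # drop duplicate consecutive vertices introduced by on-line points
  if (nrow(out) >= 2) {
    nn <- nrow(out)
    dup <- rowSums((out - out[c(nn, 1:(nn - 1)), , drop = FALSE])^2) < 1e-20
    out <- out[!dup, , drop = FALSE]
  }
  if (nrow(out) < 3 || polygon_area(out, check_simple = FALSE) < 1e-12) {
    stop_geometry("degenerate clip: polygon has no area on the vessel side")
  }
  out
}

#' Boundary radius along an azimuth
#'
#' Distance from `origin` to the polygon boundary along the ray at angle
#' `theta` (radians, measured from the +x axis). Intended for star-shaped
#' contours; if the ray crosses the boundary more than once (a slightly
#' folded traced contour) the nearest intersection is returned with a
#' warning. No intersection at all is a geometry error.
#'
#' @param polygon An n x 2 vertex matrix (mm).
#' @param origin Ray origin (mm), strictly inside the polygon.
#' @param theta Azimuth in radians.
#' @return Radius in mm.
#' @examples
#' sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
#' boundary_radius_at_azimuth(sq, c(0, 0), 0) # 1
#' @export
boundary_radius_at_azimuth <- function(polygon, origin = c(0, 0), theta) {
  p <- as_polygon(polygon)
  if (!point_in_polygon(origin, p)) {
    stop_geometry("`origin` lies outside the polygon")
  }
  n <- nrow(p)
  a <- cbind(p[, 1] - origin[1], p[, 2] - origin[2])
  b <- a[c(2:n, 1), , drop = FALSE]
  e <- b - a
  dir <- c(cos(theta), sin(theta))
  denom <- dir[1] * e[, 2] - dir[2] * e[, 1]
  ok <- abs(denom) > 1e-14
  t <- (a[, 1] * e[, 2] - a[, 2] * e[, 1]) / denom
  s <- (a[, 1] * dir[2] - a[, 2] * dir[1]) / denom
  hit <- ok & t > 1e-9 & s >= 0 & s < 1
  if (!any(hit)) {
    stop_geometry(sprintf(
      "no boundary intersection along azimuth %.4f rad", theta))
  }
  tt <- sort(t[hit])
  # collapse near-identical hits (vertex shared by two edges)
  tt <- tt[c(TRUE, diff(tt) > 1e-9)]
  if (length(tt) > 1) {
    warn(sprintf(
      "polygon is not star-shaped about the origin at azimuth %.4f rad; using nearest of %d intersections",
      theta, length(tt)))
  }
  tt[1]
}

#' Fraction of the vessel cross section enclosed by the ablation
#'
#' Area of the intersection between the polygon and the vessel disc, divided
#' by the disc area. Computed exactly by summing per-edge contributions of
#' triangle/circular-sector pieces (no sampling).
#'
#' @param polygon An n x 2 vertex matrix (mm).
#' @param vessel_centre Disc centre (mm).
#' @param vessel_outer_radius Disc radius in mm (> 0).
#' @return Enclosure fraction in `[0, 1]`.
#' @examples
#' sq <- rbind(c(10, 10), c(-10, 10), c(-10, -10), c(10, -10))
#' vessel_enclosure_fraction(sq, c(0, 0), 1)   # 1: disc inside
#' vessel_enclosure_fraction(sq, c(10, 0), 1)  # 0.5: centre on an edge
#' @export
vessel_enclosure_fraction <- function(polygon, vessel_centre = c(1, 0),
                                      vessel_outer_radius = 2.5) {
  if (!is.finite(vessel_outer_radius) || vessel_outer_radius <= 0) {
    stop_parameter("`vessel_outer_radius` must be > 0")
  }
  p <- as_polygon(polygon)
  inter <- abs(circle_polygon_intersection_area(
    sweep(p, 2, as.numeric(vessel_centre)), vessel_outer_radius))
  min(1, max(0, inter / (pi * vessel_outer_radius^2)))
}

# Signed area of the intersection of disc(0, r) with a polygon, as the sum
# over directed edges A->B of area(disc %intersect% triangle(O, A, B)),
# signed by edge orientation. Each edge contributes its inside sub-segment
# as a triangle and its outside parts as circular sectors. Vectorised over
# edges.
circle_polygon_intersection_area <- function(p, r) {
  n <- nrow(p)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- p[c(2:n, 1), 1]; by <- p[c(2:n, 1), 2]
  dx <- bx - ax; dy <- by - ay
  a2 <- dx^2 + dy^2
  bq <- ax * dx + ay * dy
  cq <- ax^2 + ay^2 - r^2
  disc <- bq^2 - a2 * cq

  sector <- function(ux, uy, vx, vy) {
    0.5 * r^2 * atan2(ux * vy - uy * vx, ux * vx + uy * vy)
  }

  area <- numeric(n)
  degenerate <- a2 < 1e-300
  # default: whole segment outside the disc -> pure sector
  area_out <- sector(ax, ay, bx, by)
  # candidate chord interval [tl, th] within [0, 1]
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-bq - sq) / a2
  t2 <- (-bq + sq) / a2
  tl <- pmax(t1, 0); th <- pmin(t2, 1)
  has_chord <- disc > 0 & th > tl & !degenerate
  p1x <- ax + tl * dx; p1y <- ay + tl * dy
  p2x <- ax + th * dx; p2y <- ay + th * dy
  area_mix <- sector(ax, ay, p1x, p1y) +
    0.5 * (p1x * p2y - p1y * p2x) +
    sector(p2x, p2y, bx, by)
  area <- ifelse(degenerate, 0, ifelse(has_chord, area_mix, area_out))
  sum(area)
}

#' Measure every white-zone slice of a slice table
#'
#' Runs the full per-slice planimetry over a slice table (see
#' [read_slice_table()] or [simulate_study()] for the format): white-zone
#' area, maximum radius from the antenna, vessel-half area, idealized
#' half-disc area, cooling area, indentation ratio at the vessel azimuth,
#' vessel enclosure fraction, the four-level cooling type, and the 3D
#' vessel-to-ablation-centre distance `rho_mm = sqrt(d^2 + z^2)`.
#'
#' @param slices A slice table (tibble): one row per traced contour with
#'   columns `run_id`, `av_distance_mm`, `flow_ml_min`, `replicate`,
#'   `offset_mm`, `zone`, `polygon` (list of vertex matrices), `antenna_x`,
#'   `antenna_y`, `vessel_x`, `vessel_y`, `vessel_outer_radius_mm`. Red-zone
#'   rows are carried through I/O but only `zone == "WZ"` rows are measured.
#' @param tau_minor,tau_moderate Indentation-ratio thresholds passed to
#'   [classify_cooling()]; defaults 0.05 and 0.20.
#' @return A tibble with one row per white-zone slice carrying the run
#'   metadata and the derived quantities (`wz_area_mm2`, `r_max_mm`,
#'   `half_area_mm2`, `idealized_half_area_mm2`, `cooling_area_mm2`,
#'   `indentation_ratio`, `enclosure_fraction`, `cooling_type`, `rho_mm`).
#' @examples
#' study <- simulate_study(study_design(5, c(0, 500), replicates = 1), seed = 1)
#' measure_slices(study$slices)
#' @export
measure_slices <- function(slices, tau_minor = 0.05, tau_moderate = 0.20) {
  required <- c("run_id", "av_distance_mm", "flow_ml_min", "replicate",
                "offset_mm", "zone", "polygon", "antenna_x", "antenna_y",
                "vessel_x", "vessel_y", "vessel_outer_radius_mm")
  missing_cols <- setdiff(required, names(slices))
  if (length(missing_cols) > 0) {
    stop_data(paste0("slice table is missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  }
  wz <- dplyr::filter(slices, .data$zone == "WZ")
  if (nrow(wz) == 0) stop_data("slice table contains no white-zone rows")

  meas <- purrr::pmap(
    list(wz$polygon, wz$antenna_x, wz$antenna_y, wz$vessel_x, wz$vessel_y,
         wz$vessel_outer_radius_mm),
    function(poly, axp, ayp, vx, vy, vr) {
      p <- as_polygon(poly)
      antenna <- c(axp, ayp)
      vessel <- c(vx, vy)
      area <- polygon_area(p, check_simple = FALSE)
      rmax <- max_radius(p, antenna)
      half <- vessel_half(p, antenna, vessel)
      half_area <- polygon_area(half, check_simple = FALSE)
      ideal <- idealized_half_area(rmax)
      theta_v <- atan2(vy - ayp, vx - axp)
      r_az <- boundary_radius_at_azimuth(p, antenna, theta_v)
      iota <- min(1, max(0, 1 - r_az / rmax))
      f <- vessel_enclosure_fraction(p, vessel, vr)
      list(wz_area_mm2 = area, r_max_mm = rmax, half_area_mm2 = half_area,
           idealized_half_area_mm2 = ideal,
           cooling_area_mm2 = cooling_area(half_area, ideal),
           indentation_ratio = iota, enclosure_fraction = f)
    })
  out <- dplyr::bind_cols(
    wz[, c("run_id", "av_distance_mm", "flow_ml_min", "replicate",
           "offset_mm")],
    dplyr::bind_rows(lapply(meas, as_tibble))
  )
  out$cooling_type <- classify_cooling(out$indentation_ratio,
                                       out$enclosure_fraction,
                                       tau_minor = tau_minor,
                                       tau_moderate = tau_moderate)
  out$rho_mm <- sqrt(out$av_distance_mm^2 + out$offset_mm^2)
  dplyr::arrange(out, .data$run_id, .data$offset_mm)
}
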