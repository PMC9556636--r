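# Geometry fixtures and independent oracles used across the suite.

regular_polygon <- function(r, n, centre = c(0, 0), start = 0) {
  th <- start + 2 * pi * (seq_len(n) - 1) / n
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# random star-shaped polygon about `centre` with log-normal-ish radii
random_star_polygon <- function(n = 40, centre = c(0, 0), r_base = 10,
                                wobble = 0.3) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- r_base * exp(stats::rnorm(n, 0, wobble))
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Monte-Carlo area oracle: uniform points in the bounding box, crossing-number
# inclusion test written independently of the package internals.
mc_point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- (yi > py) != (yj > py)
    xint <- (xj - xi) * (py - yi) / (yj - yi) + xi
    inside <- xor(inside, cross & px < xint)
    j <- i
  }
  inside
}

mc_polygon_area <- function(poly, n_points = 1e6) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  px <- stats::runif(n_points, xr[1], xr[2])
  py <- stats::runif(n_points, yr[1], yr[2])
  mean(mc_point_in_poly(px, py, poly)) * diff(xr) * diff(yr)
}

# MC disc-polygon overlap oracle (fraction of the disc inside the polygon)
mc_enclosure_fraction <- function(poly, centre, radius, n_points = 2e5) {
  u <- stats::runif(n_points); th <- stats::runif(n_points, 0, 2 * pi)
  r <- radius * sqrt(u)
  px <- centre[1] + r * cos(th); py <- centre[2] + r * sin(th)
  mean(mc_point_in_poly(px, py, poly))
}

# noise-free phantom shortcut
quiet_params <- function(..., seed = 1) {
  phantom_params(..., seed = seed, boundary_noise_sd_mm = 0,
                 size_jitter_sd = 0)
}
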