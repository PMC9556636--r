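test_that("shoelace area matches closed forms regardless of orientation", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_area(sq[4:1, ]), 1)  # clockwise
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  # regular 64-gon, circumradius 10: (n/2) R^2 sin(2 pi / n)
  p64 <- regular_polygon(10, 64)
  expect_equal(polygon_area(p64), 32 * 100 * sin(2 * pi / 64),
               tolerance = 1e-12)
  expect_equal(polygon_area(p64), 313.65, tolerance = 1e-4)
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))),
               class = "mwacool_geometry_error")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(polygon_area(bowtie), class = "mwacool_geometry_error")
  expect_error(polygon_area(rbind(c(0, 0), c(1, NA), c(1, 1))),
               class = "mwacool_geometry_error")
})

test_that("maximum radius is measured from the reference point", {
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  expect_equal(max_radius(sq, c(0, 0)), sqrt(2))
  p64 <- regular_polygon(10, 64)
  expect_equal(max_radius(p64, c(0, 0)), 10)
  # off-centre origin: brute-force over vertices is the oracle
  origin <- c(3, 0)
  brute <- max(sqrt((p64[, 1] - 3)^2 + p64[, 2]^2))
  expect_equal(max_radius(p64, origin), brute)
  expect_equal(max_radius(p64, origin), 13)
  expect_error(max_radius(p64, c(20, 0)), class = "mwacool_geometry_error")
})

test_that("vessel-half clipping keeps the vessel side of the antenna plane", {
  circ <- regular_polygon(10, 512)
  half <- vessel_half(circ, c(0, 0), c(5, 0))
  expect_equal(polygon_area(half), 50 * pi, tolerance = 1e-3)
  expect_true(all(half[, 1] >= -1e-9))
  # polygon entirely on the vessel side is returned unchanged (same area)
  right <- regular_polygon(1, 16, centre = c(5, 0))
  expect_equal(polygon_area(vessel_half(right, c(0, 0), c(5, 0))),
               polygon_area(right))
  # degenerate clip: everything on the far side
  expect_error(vessel_half(right, c(10, 0), c(15, 0)),
               class = "mwacool_geometry_error")
  expect_error(vessel_half(circ, c(0, 0), c(0, 0)),
               class = "mwacool_parameter_error")
})

test_that("half areas are additive and match a Monte-Carlo oracle", {
  withr::with_seed(11, {
    for (i in 1:10) {
      p <- random_star_polygon(n = sample(20:60, 1))
      vessel <- c(runif(1, 2, 8), runif(1, -2, 2))
      h1 <- vessel_half(p, c(0, 0), vessel)
      h2 <- vessel_half(p, c(0, 0), -vessel)
      expect_equal(polygon_area(h1) + polygon_area(h2), polygon_area(p),
                   tolerance = 1e-6)
    }
  })
  # clipped area of a notched phantom slice against 1e6-point Monte Carlo
  stack <- generate_stack(quiet_params(av_distance_mm = 5, flow_ml_min = 500,
                                       polygon_vertices_per_slice = 256,
                                       seed = 5))
  slice <- stack$slices$polygon[[which(stack$slices$offset_mm == 6 &
                                         stack$slices$zone == "WZ")]]
  half <- vessel_half(slice, c(0, 0), c(5, 0))
  withr::with_seed(99, {
    expect_equal(polygon_area(half), mc_polygon_area(half, 1e6),
                 tolerance = 5e-3)
  })
})

test_that("boundary radius along an azimuth matches known geometry", {
  circ <- regular_polygon(10, 720)
  for (th in c(0, 0.7, 2, -2.5)) {
    expect_equal(boundary_radius_at_azimuth(circ, c(0, 0), th), 10,
                 tolerance = 1e-4)
  }
  sq <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  expect_equal(boundary_radius_at_azimuth(sq, c(0, 0), 0), 1)
  expect_equal(boundary_radius_at_azimuth(sq, c(0, 0), pi / 4), sqrt(2),
               tolerance = 1e-12)
  # generated phantom: the notch depth at the vessel azimuth recovers kappa
  pp <- quiet_params(av_distance_mm = 5, flow_ml_min = 500,
                     notch_depth_max = 0.3, border_sigma_mm = 100,
                     polygon_vertices_per_slice = 512, seed = 2)
  stack <- generate_stack(pp)
  wz <- stack$slices[stack$slices$zone == "WZ" & stack$slices$offset_mm == 0, ]
  truth_k <- stack$truth$slice_truth$kappa[
    stack$truth$slice_truth$offset_mm == 0]
  r0 <- 16  # no jitter
  r_az <- boundary_radius_at_azimuth(wz$polygon[[1]], c(0, 0), 0)
  expect_equal(r_az, r0 * (1 - truth_k), tolerance = 1e-3)
})

test_that("a folded contour warns and uses the nearest crossing", {
  # comb-shaped contour crossing the +x ray from (2, 0) at x = 3, 4.5 and 6
  fold <- rbind(c(1, -2), c(6, -2), c(6, 0.8), c(4.5, 0.8), c(4.5, -0.3),
                c(3, -0.3), c(3, 2), c(1, 2))
  expect_warning(r <- boundary_radius_at_azimuth(fold, c(2, 0), 0),
                 regexp = "not star-shaped")
  expect_equal(r, 1, tolerance = 1e-9)
  # origin outside the contour is a geometry error
  expect_error(
    boundary_radius_at_azimuth(rbind(c(1, 1), c(2, 1), c(2, 2), c(1, 2)),
                               origin = c(5, 5), theta = 0),
    class = "mwacool_geometry_error")
  # max radius bounds the radius at every azimuth (random star polygons)
  withr::with_seed(3, {
    for (i in 1:5) {
      p <- random_star_polygon(n = 50)
      rmax <- max_radius(p, c(0, 0))
      for (th in runif(20, -pi, pi)) {
        expect_lte(boundary_radius_at_azimuth(p, c(0, 0), th), rmax + 1e-9)
      }
    }
  })
})

test_that("vessel enclosure fraction is exact on closed-form cases", {
  big <- rbind(c(50, 50), c(-50, 50), c(-50, -50), c(50, -50))
  expect_equal(vessel_enclosure_fraction(big, c(0, 0), 2.5), 1)
  expect_equal(vessel_enclosure_fraction(big, c(100, 0), 2.5), 0)
  # disc centre on a long straight edge: exactly half
  expect_equal(vessel_enclosure_fraction(big, c(50, 0), 2.5), 0.5,
               tolerance = 1e-9)
  # off-edge offsets: circular-segment closed form (off > 0: centre outside)
  for (off in c(-1.5, 0.8)) {
    r <- 2.5
    seg <- (r^2 * acos(off / r) - off * sqrt(r^2 - off^2)) / (pi * r^2)
    expect_equal(vessel_enclosure_fraction(big, c(50 + off, 0), r), seg,
                 tolerance = 1e-9)
  }
  expect_error(vessel_enclosure_fraction(big, c(0, 0), 0),
               class = "mwacool_parameter_error")
})

test_that("enclosure fraction agrees with Monte-Carlo on irregular contours", {
  withr::with_seed(21, {
    for (i in 1:6) {
      p <- random_star_polygon(n = 40)
      centre <- c(runif(1, 4, 11), runif(1, -4, 4))
      f <- vessel_enclosure_fraction(p, centre, 2.5)
      f_mc <- mc_enclosure_fraction(p, centre, 2.5, n_points = 2e5)
      expect_lt(abs(f - f_mc), 4e-3)
    }
  })
})

test_that("measure_slices produces coherent per-slice quantities", {
  stack <- generate_stack(phantom_params(av_distance_mm = 5,
                                         flow_ml_min = 100, seed = 8))
  m <- measure_slices(stack$slices)
  expect_equal(nrow(m), sum(stack$slices$zone == "WZ"))
  expect_true(all(m$half_area_mm2 <= m$wz_area_mm2 + 1e-9))
  expect_true(all(m$cooling_area_mm2 >= 0))
  expect_true(all(m$cooling_area_mm2 <= m$idealized_half_area_mm2 + 1e-9))
  expect_true(all(m$indentation_ratio >= 0 & m$indentation_ratio <= 1))
  expect_true(all(m$enclosure_fraction >= 0 & m$enclosure_fraction <= 1))
  expect_true(all(m$cooling_type %in% 0:3))
  expect_equal(m$rho_mm, sqrt(m$av_distance_mm^2 + m$offset_mm^2))
  expect_error(measure_slices(m[0, ]), class = "mwacool_data_error")
})
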