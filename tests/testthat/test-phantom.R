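test_that("parameter validation guards the generative law", {
  expect_error(phantom_params(seed = 1, notch_depth_max = 1),
               class = "mwacool_parameter_error")
  expect_error(phantom_params(seed = 1, av_distance_mm = 0),
               class = "mwacool_parameter_error")
  expect_error(phantom_params(seed = 1, polygon_vertices_per_slice = 8),
               class = "mwacool_parameter_error")
  expect_error(phantom_params(av_distance_mm = 5),
               class = "mwacool_parameter_error")  # missing seed
  expect_error(phantom_params(seed = 1, vessel_inner_radius_mm = 3,
                              vessel_outer_radius_mm = 2.5),
               class = "mwacool_parameter_error")
})

test_that("zero notch depth yields circular slices with zero true cooling", {
  stack <- generate_stack(quiet_params(notch_depth_max = 0,
                                       flow_ml_min = 500, seed = 4))
  expect_equal(stack$truth$cooling_volume_ml, 0, tolerance = 1e-9)
  wz <- stack$slices[stack$slices$zone == "WZ", ]
  radii <- vapply(wz$polygon, function(p) {
    r <- sqrt(rowSums(p^2)); diff(range(r))
  }, numeric(1))
  expect_true(all(radii < 1e-9))  # noise-free circles
})

test_that("no perfusion means no indentation and all slices Type 0", {
  stack <- generate_stack(quiet_params(av_distance_mm = 2.5,
                                       flow_ml_min = 0, seed = 6))
  expect_equal(stack$truth$cooling_volume_ml, 0, tolerance = 1e-9)
  expect_true(all(stack$truth$slice_truth$true_cooling_type == 0))
  m <- measure_slices(stack$slices)
  expect_true(all(m$cooling_type == 0))
  # chord-vs-arc discretization bounds the residual indentation
  expect_true(all(m$indentation_ratio < 1e-3))
})

test_that("slice placement follows the sectioning protocol", {
  pp <- phantom_params(av_distance_mm = 5, flow_ml_min = 10, seed = 9)
  stack <- generate_stack(pp)
  wz <- stack$slices[stack$slices$zone == "WZ", ]
  expect_true(all(abs(wz$offset_mm %% pp$slice_spacing_mm) < 1e-9))
  expect_true(all(abs(wz$offset_mm) <= pp$axial_extent_mm))
  # traceability cutoff: no vanishingly small polar sections
  areas <- vapply(wz$polygon, polygon_area, numeric(1), check_simple = FALSE)
  expect_true(all(areas > 0.5 * pi * pp$min_traceable_radius_mm^2))
  # one WZ and one RZ contour per offset, RZ radially outside WZ
  expect_equal(sum(stack$slices$zone == "RZ"), nrow(wz))
})

test_that("generation is reproducible under the seed and varies across seeds", {
  pp <- phantom_params(av_distance_mm = 5, flow_ml_min = 100, seed = 123)
  s1 <- generate_stack(pp)
  s2 <- generate_stack(pp)
  expect_identical(s1$slices$polygon, s2$slices$polygon)
  s3 <- generate_stack(phantom_params(av_distance_mm = 5, flow_ml_min = 100,
                                      seed = 124))
  expect_false(identical(s1$slices$polygon, s3$slices$polygon))
})

test_that("noise-free pipeline volume recovers the analytic half-ellipsoid", {
  stack <- generate_stack(quiet_params(flow_ml_min = 0,
                                       polygon_vertices_per_slice = 512,
                                       seed = 10))
  r <- stack_reports(measure_slices(stack$slices))
  expect_equal(r$ablation_volume_ml, stack$truth$half_ablation_volume_ml,
               tolerance = 0.02)
})

test_that("true cooling volume is monotone in flow and in notch depth", {
  vols_q <- vapply(c(0, 1, 2, 5, 10, 100, 500), function(q) {
    generate_stack(quiet_params(av_distance_mm = 5, flow_ml_min = q,
                                seed = 1))$truth$cooling_volume_ml
  }, numeric(1))
  expect_true(all(diff(vols_q) >= -1e-12))
  vols_k <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(k) {
    generate_stack(quiet_params(av_distance_mm = 5, flow_ml_min = 100,
                                notch_depth_max = k,
                                seed = 1))$truth$cooling_volume_ml
  }, numeric(1))
  expect_true(all(diff(vols_k) > 0))
})

test_that("every generated contour is simple and star-shaped about the antenna", {
  for (seed in 1:3) {
    stack <- generate_stack(phantom_params(av_distance_mm = 2.5,
                                           flow_ml_min = 500, seed = seed))
    for (p in stack$slices$polygon) {
      th <- atan2(p[, 2], p[, 1])
      d <- diff(th)
      d <- ifelse(d <= -pi, d + 2 * pi, d)
      expect_true(all(d > 0))  # strictly increasing azimuth = star-shaped
    }
  }
})

test_that("peripheral slices cool more than central ones for Q >= 2", {
  m <- get_full_measurements()
  for (q in c(2, 5, 10, 100, 500)) {
    mq <- m[m$flow_ml_min == q, ]
    periph <- mean(mq$cooling_type[abs(mq$rho_mm - 7.5) <= 1])
    central <- mean(mq$cooling_type[abs(mq$rho_mm - 2.5) <= 1])
    expect_gt(periph, central)
  }
})

test_that("coolant temperature draws are seeded, truncated and centred", {
  d1 <- generate_delta_t(500, n = 6, seed = 31)
  d2 <- generate_delta_t(500, n = 6, seed = 31)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  expect_equal(generate_delta_t(100, n = 5, seed = 1, sd_K = 0),
               rep(0.6, 5))
  big <- generate_delta_t(100, n = 1e4, seed = 17)
  expect_lt(abs(median(big) - 0.6), 0.02)
  expect_error(generate_delta_t(10, n = 3, seed = 1),
               class = "mwacool_parameter_error")
  expect_error(generate_delta_t(100, n = 0, seed = 1),
               class = "mwacool_parameter_error")
})
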