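# Wall-motion generation: frame counts, the ejection-fraction contract,
# cyclic consistency, and the periodic spline interpolation.

test_that("motion frames deliver the prescribed ejection fraction", {
  g <- heart_geom_h()
  mo <- heart_motion_h()
  expect_equal(dim(mo$frames)[3], g$params$n_frames)
  # reference (end-systolic) frame has identically zero displacement
  expect_equal(max(abs(mo$frames[, , mo$reference_frame])), 0)
  v <- frame_volumes(g, mo, "LV")
  ef <- (max(v) - min(v)) / max(v)
  expect_lt(abs(ef - g$params$ejection_fraction), 0.02)
  # recomputed frame volumes match the calibration targets
  expect_equal(v, mo$v_lv_target, tolerance = 1e-4)
})

test_that("volume is continuous across the cycle wrap-around", {
  g <- heart_geom_h()
  mo <- heart_motion_h()
  cm <- continuous_motion(mo)
  lv_surf <- lhflow:::region_closed_surface(g$mesh, g$cell_region == 1L)
  vol_at <- function(t) {
    pts <- g$mesh$points
    pts[mo$bnodes, ] <- pts[mo$bnodes, ] + interpolate_displacement(cm, t)
    surface_enclosed_volume(pts, lv_surf)
  }
  # interpolate between the last frame and the wrap to frame 1
  t_half <- mo$frame_times[mo$n_frames] + 0.5 * mo$period_T / mo$n_frames
  v_wrap <- vol_at(t_half)
  v_1 <- vol_at(0)
  expect_lt(abs(v_wrap - v_1) / v_1, 0.005)
})

test_that("periodic spline interpolates frames exactly and periodically", {
  mo <- heart_motion_h()
  cm <- continuous_motion(mo)
  k <- 7L
  expect_equal(interpolate_displacement(cm, mo$frame_times[k]),
               mo$frames[, , k], tolerance = 1e-12)
  expect_equal(interpolate_displacement(cm, mo$period_T),
               interpolate_displacement(cm, 0), tolerance = 1e-12)
})

test_that("spline reconstruction error of a sampled sinusoid is small", {
  T <- 0.8
  n <- 30L
  tt <- (seq_len(n) - 1) * T / n
  amp <- c(1, 0.3, -2) # three signal components with different amplitudes
  vals <- outer(sin(2 * pi * tt / T), amp)
  ps <- periodic_spline(vals, T)
  t_test <- tt + T / (2 * n) # mid-interval points
  err <- vapply(seq_along(t_test), function(i) {
    max(abs(eval_periodic_spline(ps, t_test[i]) -
              sin(2 * pi * t_test[i] / T) * amp))
  }, numeric(1))
  expect_lt(max(err), 1e-3 * max(abs(amp)))
})

test_that("too few frames degrade to linear interpolation with a warning", {
  expect_warning(ps <- periodic_spline(cbind(c(0, 1, 0)), 1), "linear")
  expect_equal(eval_periodic_spline(ps, 1 / 6), 0.5)
})

test_that("unreachable ejection fraction is rejected", {
  g <- heart_geom_h()
  params <- g$params
  params$ejection_fraction <- 0.97
  expect_error(generate_motion(g, params), "unreachable")
})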