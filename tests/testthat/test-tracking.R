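test_that("ROI subdivision tiles exactly with remainder to the last cells", {
  r <- roi(0, 0, 100, 60)
  tiles <- subdivide_roi(r, 2, 2)
  expect_length(tiles, 4)
  expect_equal(vapply(tiles, function(t) (t$x1 - t$x0) * (t$y1 - t$y0),
                      numeric(1)), rep(50 * 30, 4))
  # 101 wide: widths 50 and 51
  t2 <- subdivide_roi(roi(0, 0, 101, 60), 2, 2)
  expect_equal(sort(unique(vapply(t2, function(t) t$x1 - t$x0,
                                  numeric(1)))), c(50, 51))
  # union area always equals the ROI area
  expect_equal(sum(vapply(t2, function(t) (t$x1 - t$x0) * (t$y1 - t$y0),
                          numeric(1))), 101 * 60)
  # identity case
  expect_equal(subdivide_roi(r, 1, 1)[[1]], r)
  expect_error(subdivide_roi(roi(0, 0, 7, 7), 2, 2), "4x4")
})

test_that("phase correlation recovers constructed shifts", {
  set.seed(11)
  a <- matrix(rnorm(64 * 64), 64, 64)
  expect_equal(unname(phase_correlation_shift(a, a)), c(0, 0),
               tolerance = 1e-6)
  # integer roll: content moves +3 in x, -2 in y
  b <- a[c(3:64, 1:2), c(62:64, 1:61)]
  expect_equal(unname(phase_correlation_shift(a, b)), c(3, -2),
               tolerance = 0.05)
  # fractional shift rendered by interpolation
  tr <- displacement_trace(c(0, 0.1), c(0, 1.5))
  sv <- synth_video(video_synthesis_spec(tr, size = c(96, 96),
                                         noise_scale = 0, seed = 2))
  sh <- phase_correlation_shift(sv$stack$frames[[1]], sv$stack$frames[[2]])
  expect_equal(unname(sh), c(1.5, 0), tolerance = 0.1)
  expect_error(phase_correlation_shift(matrix(1, 8, 8), matrix(1, 8, 8)),
               "degenerate")
})

test_that("tracker reproduces rigid global shifts within 0.25 px", {
  sv <- rigid_video()
  out <- track_displacement(sv$stack, roi(16, 16, 80, 80))
  expect_s3_class(out, "displacement_trace")
  expect_equal(out$displacement[1], 0)
  expect_lt(max(abs(out$displacement - sv$trace$displacement)), 0.25)
  expect_true(all(out$n_points_alive[-1] >= 5))
})

test_that("tracker is quiet on a static stack", {
  tt <- seq(0, 1.9, by = 0.1)
  sv <- synth_video(video_synthesis_spec(
    displacement_trace(tt, rep(0, length(tt))), size = c(96, 96), seed = 8))
  out <- track_displacement(sv$stack, roi(16, 16, 80, 80))
  expect_lt(max(out$displacement), 0.2)
})

test_that("trace is invariant to intensity offset and mirror symmetric", {
  sv <- rigid_video(disp = c(0, 1, 2, 1, 0), seed = 4)
  base <- track_displacement(sv$stack, roi(16, 16, 80, 80))
  shifted <- frame_stack(lapply(sv$stack$frames, function(f) f + 5),
                         sv$stack$frame_interval)
  out2 <- track_displacement(shifted, roi(16, 16, 80, 80))
  expect_equal(out2$displacement, base$displacement, tolerance = 1e-6)
  # mirrored stack: unsigned displacement unchanged (within tracker noise)
  mir <- frame_stack(lapply(sv$stack$frames, function(f) f[, ncol(f):1]),
                     sv$stack$frame_interval)
  out3 <- track_displacement(mir, roi(16, 16, 80, 80))
  expect_lt(max(abs(out3$displacement - base$displacement)), 0.1)
})

test_that("degenerate tracking inputs raise the documented errors", {
  # featureless (constant) ROI: no corners to track
  flat <- frame_stack(replicate(3, matrix(1, 64, 64), simplify = FALSE),
                      0.1)
  expect_error(track_displacement(flat, roi(8, 8, 56, 56)),
               "insufficient features")
  expect_error(track_displacement(rigid_video(disp = c(0, 1))$stack,
                                  roi(0, 0, 200, 200)), "bounds")
})

test_that("physical-unit conversion scales and round-trips", {
  tr <- displacement_trace(c(0, 0.1, 0.2), c(0, 1, 2))
  um <- to_physical_units(tr, 0.5)
  expect_equal(um$displacement, c(0, 0.5, 1.0))
  expect_equal(um$units, "um")
  expect_error(to_physical_units(um, 0.5), "physical")
  id <- to_physical_units(tr, 1.0)
  expect_equal(id$displacement, tr$displacement)
})
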