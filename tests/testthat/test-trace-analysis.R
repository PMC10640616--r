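test_that("baseline correction removes offsets and linear drift", {
  tt <- seq(0, 60, by = 0.1)
  # constant offset after frame 0
  y <- c(0, rep(2, length(tt) - 1))
  tr <- baseline_correct(displacement_trace(tt, y), 20, detrend = FALSE)
  expect_lt(abs(stats::median(tr$displacement[tr$times < 20])), 1e-9)
  # zero trace stays zero
  z <- baseline_correct(displacement_trace(tt, rep(0, length(tt))), 20)
  expect_equal(z$displacement, rep(0, length(tt)))
  # linear drift 0.1 units/s, no events: corrected max < 0.05
  dr <- displacement_trace(tt, 0.1 * tt)
  cor <- baseline_correct(dr, 20)
  expect_lt(max(cor$displacement), 0.05)
  expect_error(baseline_correct(dr, -1), "pre-stimulus")
})

test_that("detector finds seeded transients and rejects noise", {
  gen <- synth_trace(trace_synthesis_spec("A", proto_05, seed = 9))
  res <- analyse_cell(gen, proto_05)
  # all 15 events, each within one frame (0.1 s) of the ground truth
  expect_length(res$events$peak_times, length(gen$event_times))
  expect_lt(max(abs(res$events$peak_times - gen$event_times)), 0.1 + 1e-9)
  # flat noise-only trace: no events
  flat <- synth_trace(trace_synthesis_spec("A", proto_05, amplitude = 0,
                                           seed = 9))
  ev0 <- detect_contractions(baseline_correct(flat$trace, 20),
                             default_peak_params(proto_05))
  expect_length(ev0$peak_times, 0)
})

test_that("minimum-distance suppression keeps the higher of close peaks", {
  # two clean transients 0.3 s apart, min_distance 0.5 s: keep the larger
  tt <- seq(0, 10, by = 0.05)
  y <- 2.0 * transient_shape_for_test(tt - 4.0) +
       3.0 * transient_shape_for_test(tt - 4.3)
  tr <- displacement_trace(tt, y)
  ev <- detect_contractions(tr, peak_params(min_distance_s = 0.5,
                                            prominence_k = 0,
                                            smoothing_frames = 1))
  expect_length(ev$peak_times, 1)
  # brute-force oracle: the surviving peak is the taller candidate
  expect_equal(ev$peak_times, tt[which.max(y)], tolerance = 0.05)
  # with a smaller min_distance both survive
  ev2 <- detect_contractions(tr, peak_params(min_distance_s = 0.2,
                                             prominence_k = 0,
                                             smoothing_frames = 1))
  expect_length(ev2$peak_times, 2)
})

test_that("detection is scale invariant and cross-checks pracma", {
  skip_if_not_installed("pracma")
  gen <- synth_trace(trace_synthesis_spec("A", proto_1, seed = 4))
  tr <- baseline_correct(gen$trace, 20)
  pp <- default_peak_params(proto_1)
  ev <- detect_contractions(tr, pp)
  # positive rescaling of trace and min_amplitude leaves peaks unchanged
  tr10 <- displacement_trace(tr$times, tr$displacement * 10,
                             tr$n_points_alive)
  pp10 <- pp; pp10$min_amplitude <- pp$min_amplitude * 10
  ev10 <- detect_contractions(tr10, pp10)
  expect_equal(ev10$peak_times, ev$peak_times)
  expect_equal(ev10$peak_amplitudes, 10 * ev$peak_amplitudes)
  # independent detector agrees on the count for a clean trace
  sm <- stats::filter(tr$displacement, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  pk <- pracma::findpeaks(as.numeric(sm), minpeakheight = 1,
                          minpeakdistance = 5)
  expect_equal(length(ev$peak_times), nrow(pk))
})

test_that("mean frequency is the reciprocal mean period", {
  ev <- contraction_events(c(0, 2, 4, 6), rep(1, 4))
  expect_equal(mean_frequency(ev), 0.5)
  # periods 1, 1, 2 -> mean period 4/3 -> 0.75 Hz
  ev2 <- contraction_events(c(0, 1, 2, 4), rep(1, 4))
  expect_equal(mean_frequency(ev2), 0.75)
  # perfect 1 Hz entrainment: peaks at 20..49
  ev3 <- contraction_events(20:49, rep(1, 30))
  expect_equal(mean_frequency(ev3), 1.0)
  expect_error(mean_frequency(contraction_events(5, 1)), "fewer than 2")
})

test_that("frequency estimates covary with the time unit", {
  gen <- synth_trace(trace_synthesis_spec("A", proto_05, seed = 3))
  res <- analyse_cell(gen, proto_05)
  f1 <- res$frequency
  # same events on a 10x slower clock
  ev_slow <- contraction_events(10 * res$events$peak_times,
                                res$events$peak_amplitudes)
  expect_equal(mean_frequency(ev_slow), f1 / 10)
})

test_that("recovered frequency tracks the generator within 2% under jitter", {
  # jitter at 10% of the period for 0.5 and 1 Hz, 5% at 2 Hz (10 fps
  # sampling cannot separate 2 Hz transients at 50 ms jitter)
  cases <- list(list(p = proto_05, jit = 0.20), list(p = proto_1, jit = 0.10),
                list(p = proto_2, jit = 0.025))
  for (cs in cases) {
    for (s in 1:5) {
      gen <- synth_trace(trace_synthesis_spec(
        "A", cs$p, latency_jitter_sd = cs$jit, seed = s))
      f <- analyse_cell(gen, cs$p)$frequency
      expect_lt(abs(f / cs$p$frequency - 1), 0.02)
    }
  }
})
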