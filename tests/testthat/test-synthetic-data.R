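test_that("trace generation is deterministic and bookkeeps its events", {
  sp <- trace_synthesis_spec("A", proto_05, seed = 42)
  g1 <- synth_trace(sp)
  g2 <- synth_trace(sp)
  expect_identical(g1$trace$displacement, g2$trace$displacement)
  expect_identical(g1$event_times, g2$event_times)
  expect_length(g1$event_times, 15)
  expect_equal(g1$class, "A")
  # events lie inside the train and after their pulse onsets
  on <- pulse_onsets(proto_05)
  expect_true(all(g1$event_times > on[1]))
  # amplitude 0: flat trace, nothing detected
  flat <- synth_trace(trace_synthesis_spec("A", proto_05, amplitude = 0,
                                           seed = 42))
  expect_lt(max(flat$trace$displacement), 1)
  # class-structure fields are rejected for the wrong class
  expect_error(trace_synthesis_spec("A", proto_05, freeze_start_pulse = 5),
               "class E")
  expect_error(trace_synthesis_spec("C", proto_05,
                                    start_delay_pulses = 4), "B and D")
})

test_that("a frozen class-E cell shows the internal gap it was given", {
  sp <- trace_synthesis_spec("E", proto_1, freeze_start_pulse = 10,
                             freeze_length_pulses = 4, seed = 5)
  res <- analyse_cell(synth_trace(sp), proto_1)
  expect_gte(res$table$max_internal_gap, 2)
  expect_equal(res$class, "E")
})

test_that("rendered videos carry their ground truth motion", {
  sv <- rigid_video(disp = c(0, 1, 2, 1, 0), seed = 13)
  # phase-correlation oracle recovers the commanded shifts
  sh <- vapply(2:5, function(k) {
    unname(phase_correlation_shift(sv$stack$frames[[1]],
                                   sv$stack$frames[[k]])[1])
  }, numeric(1))
  expect_equal(sh, c(1, 2, 1, 0), tolerance = 0.1)
  # zero trace: frames identical up to noise
  tt <- seq(0, 0.9, by = 0.1)
  still <- synth_video(video_synthesis_spec(
    displacement_trace(tt, rep(0, 10)), size = c(64, 64), seed = 6))
  dmax <- max(abs(still$stack$frames[[1]] - still$stack$frames[[5]]))
  expect_lt(dmax, 0.2)
  # guard band on excessive displacement
  expect_error(video_synthesis_spec(
    displacement_trace(c(0, 0.1), c(0, 20)), size = c(64, 64)), "guard")
})

test_that("population generation is seeded, labelled and perturbed", {
  probs <- c(A = 1.0)
  pop <- synth_population(probs, 20,
                          base_spec = trace_synthesis_spec(protocol = proto_05),
                          seed = 3)
  expect_equal(pop$labels$true_class, rep("A", 20))
  # identical reruns
  pop2 <- synth_population(probs, 20,
                           base_spec = trace_synthesis_spec(protocol = proto_05),
                           seed = 3)
  expect_identical(pop$cells[[7]]$trace$displacement,
                   pop2$cells[[7]]$trace$displacement)
  # per-cell amplitude perturbation actually varies
  amps <- vapply(pop$cells, function(cl) cl$spec$amplitude, numeric(1))
  expect_gt(stats::sd(amps), 0)
  expect_error(synth_population(c(A = 0.5), 10), "sum to 1")
})

test_that("mixed populations with misses pace below the drive frequency", {
  probs <- c(A = 0.5, E = 0.25, F = 0.25)
  pop <- synth_population(probs, 40,
                          base_spec = trace_synthesis_spec(protocol = proto_1),
                          seed = 11)
  freqs <- vapply(pop$cells, function(cl) {
    r <- analyse_cell(cl, proto_1)
    if (is.na(r$frequency)) NA_real_ else r$frequency
  }, numeric(1))
  s <- summarize_population(freqs[!is.na(freqs)], target = 1)
  expect_lt(s$mean, 1)
})

test_that("nuclei images respect spacing and density guards", {
  img <- synth_nuclei_image(30, 5, size = c(200, 200), seed = 2)
  expect_equal(nrow(img$truth), 30)
  expect_equal(sum(img$truth$dead), 5)
  dm <- as.matrix(stats::dist(img$truth[, c("x_px", "y_px")]))
  diag(dm) <- Inf
  expect_gte(min(dm), 15)   # default min_spacing = 6 * sigma
  # dead channel blank when n_dead = 0
  img0 <- synth_nuclei_image(10, 0, size = c(128, 128), seed = 2)
  expect_equal(max(img0$channels$dead), 0)
  # impossible density errors out
  expect_error(synth_nuclei_image(500, 0, size = c(64, 64), seed = 2),
               "density")
})
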