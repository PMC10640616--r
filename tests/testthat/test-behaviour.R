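test_that("greedy matching follows the window rules", {
  # events exactly at each onset: everything matches
  ev <- contraction_events(pulse_onsets(proto_1), rep(1, 30))
  tab <- match_events(ev, proto_1)
  expect_equal(tab$matched_fraction, 1.0)
  expect_equal(tab$max_internal_gap, 0L)
  expect_equal(tab$first_matched_index, 0L)
  # events at onsets + 0.3 s for pulses 5..29, window 1 s
  on <- pulse_onsets(proto_1)
  ev2 <- contraction_events(on[6:30] + 0.3, rep(1, 25))
  tab2 <- match_events(ev2, proto_1, window = 1.0)
  expect_equal(tab2$first_matched_index, 5L)
  expect_equal(tab2$matched_fraction, 25 / 30)
  # two events inside one inter-pulse interval: first matches, second not
  p <- stimulus_protocol(1, "optical", train_start = 0, train_duration = 2)
  ev3 <- contraction_events(c(0.2, 0.6), c(1, 1))
  tab3 <- match_events(ev3, p, window = 1.0)
  expect_equal(tab3$n_matched, 1L)
  expect_equal(tab3$n_unmatched_events, 1L)
  # empty events: all-unmatched table, no error
  tab4 <- match_events(contraction_events(numeric(0), numeric(0)), proto_1)
  expect_equal(tab4$n_matched, 0L)
  expect_true(is.na(tab4$first_matched_index))
})

test_that("each event serves at most one pulse and latencies stay in window", {
  gen <- synth_trace(trace_synthesis_spec("A", proto_1, seed = 2))
  res <- analyse_cell(gen, proto_1)
  lat <- res$table$table$latency_s
  lat <- lat[!is.na(lat)]
  expect_true(all(lat >= 0 & lat <= protocol_period(proto_1)))
  matched_times <- res$table$table$event_s
  matched_times <- matched_times[!is.na(matched_times)]
  expect_equal(anyDuplicated(matched_times), 0L)
})

test_that("the decision procedure assigns the six classes as specified", {
  bp <- default_behaviour_params(proto_1)
  mk <- function(matched_idx, np = 30) {
    on <- pulse_onsets(proto_1)[seq_len(np)]
    ev <- contraction_events(on[matched_idx] + 0.2,
                             rep(1, length(matched_idx)))
    match_events(ev, proto_1)
  }
  expect_equal(classify(mk(1:30), bp), "A")
  # no events at all: F
  expect_equal(classify(match_events(contraction_events(numeric(0),
                                                        numeric(0)),
                                     proto_1), bp), "F")
  # matches for pulses 0..9 and 14..29 (0-based): internal gap of 4 -> E
  expect_equal(classify(mk(c(1:10, 15:30)), bp), "E")
  # first match at pulse 5 (0-based): delayed -> B
  expect_equal(classify(mk(6:30), bp), "B")
  # stops at pulse 24 of 30: early stop -> C
  expect_equal(classify(mk(1:25), bp), "C")
  # both -> D
  expect_equal(classify(mk(6:25), bp), "D")
  # under half matched -> F regardless of structure
  expect_equal(classify(mk(seq(1, 30, by = 3)), bp), "F")
})

test_that("adding a matched response never demotes class A", {
  bp <- default_behaviour_params(proto_1)
  on <- pulse_onsets(proto_1)
  for (drop in 1:29) {
    idx <- setdiff(1:30, drop)
    full <- match_events(contraction_events(on + 0.2, rep(1, 30)), proto_1)
    partial <- match_events(contraction_events(on[idx] + 0.2,
                                               rep(1, 29)), proto_1)
    if (classify(partial, bp) == "A") {
      expect_equal(classify(full, bp), "A")
    }
  }
})

test_that("class distribution returns percentages with sqrt(N) errors", {
  d <- behaviour_distribution(rep("A", 10))
  expect_equal(d$percent[d$class == "A"], 100)
  expect_equal(sum(d$percent), 100)
  d2 <- behaviour_distribution(c(rep("A", 5), rep("E", 3), rep("F", 2)))
  expect_equal(d2$percent[d2$class %in% c("A", "E", "F")], c(50, 30, 20))
  expect_equal(d2$error_percent[d2$class == "A"], sqrt(5))
  # permutation invariance
  set.seed(1)
  cls <- sample(c("A", "B", "F"), 40, replace = TRUE)
  expect_equal(behaviour_distribution(cls),
               behaviour_distribution(rev(cls)))
  expect_error(behaviour_distribution(character(0)), "empty")
})

test_that("empirical class fractions match generator probabilities", {
  probs <- c(A = 0.6, E = 0.2, F = 0.2)
  pop <- synth_population(probs, n = 200,
                          base_spec = trace_synthesis_spec(protocol = proto_1),
                          seed = 77)
  emp <- table(factor(pop$labels$true_class, levels = names(probs))) / 200
  se <- sqrt(probs * (1 - probs) / 200)
  expect_true(all(abs(as.numeric(emp) - probs) <= 3 * se))
})
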