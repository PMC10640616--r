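# Shared cohort definitions for the analysis scripts.
#
# Six paced cohorts emulate the study layout: optical and electrical
# stimulation at 0.5, 1 and 2 Hz with the published cohort sizes. The
# behaviour-class mixes are emulation choices (the study reports its
# distributions only graphically): entrainment degrades and transient
# freezing grows with pacing rate, and freezing is more common under
# optical pacing.

cohort_table <- function() {
  data.frame(
    cohort = c("optical_0.5Hz", "optical_1Hz", "optical_2Hz",
               "electrical_0.5Hz", "electrical_1Hz", "electrical_2Hz"),
    modality = rep(c("optical", "electrical"), each = 3),
    frequency_hz = rep(c(0.5, 1, 2), 2),
    n_cells = c(87, 114, 41, 51, 50, 32),
    stringsAsFactors = FALSE
  )
}

class_mix <- function(modality, frequency_hz) {
  key <- paste(modality, frequency_hz)
  mixes <- list(
    "optical 0.5"    = c(A = .70, B = .06, C = .06, D = .03, E = .12, F = .03),
    "optical 1"      = c(A = .55, B = .08, C = .08, D = .05, E = .16, F = .08),
    "optical 2"      = c(A = .25, B = .12, C = .15, D = .10, E = .29, F = .09),
    "electrical 0.5" = c(A = .80, B = .05, C = .05, D = .02, E = .05, F = .03),
    "electrical 1"   = c(A = .75, B = .06, C = .06, D = .03, E = .06, F = .04),
    "electrical 2"   = c(A = .40, B = .12, C = .15, D = .10, E = .13, F = .10)
  )
  mixes[[key]]
}

# deterministic per-cohort seed derived from the base seed
cohort_seed <- function(base_seed, i) base_seed * 1000L + i

make_cohort <- function(row, base_seed, i) {
  protocol <- stimulus_protocol(row$frequency_hz, row$modality,
                                amplitude = if (row$modality == "optical")
                                  42 else 3)
  pop <- synth_population(
    class_mix(row$modality, row$frequency_hz), n = row$n_cells,
    base_spec = trace_synthesis_spec(protocol = protocol),
    seed = cohort_seed(base_seed, i)
  )
  list(name = row$cohort, protocol = protocol, pop = pop)
}

analyse_one <- function(cell, protocol) {
  tr <- baseline_correct(cell$trace, protocol$train_start)
  ev <- detect_contractions(tr, default_peak_params(protocol))
  tab <- match_events(ev, protocol)
  list(class = classify(tab, default_behaviour_params(protocol)),
       frequency = if (length(ev$peak_times) >= 2) mean_frequency(ev)
                   else NA_real_,
       n_events = length(ev$peak_times))
}
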