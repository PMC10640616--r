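# shared fixtures: protocols and the standard trace-analysis chain

proto_05 <- stimulus_protocol(0.5, "optical", amplitude = 42)
proto_1 <- stimulus_protocol(1, "optical", amplitude = 42)
proto_2 <- stimulus_protocol(2, "optical", amplitude = 42)

# baseline-correct, detect, match, classify one synthetic cell
analyse_cell <- function(gen, protocol) {
  tr <- baseline_correct(gen$trace, protocol$train_start)
  ev <- detect_contractions(tr, default_peak_params(protocol))
  tab <- match_events(ev, protocol)
  list(trace = tr, events = ev, table = tab,
       class = classify(tab, default_behaviour_params(protocol)),
       frequency = if (length(ev$peak_times) >= 2) mean_frequency(ev)
                   else NA_real_)
}

# peak-normalized fast-rise slow-decay transient used to construct traces
transient_shape_for_test <- function(t, rise = 0.05, decay = 0.15) {
  tp <- rise * log(1 + decay / rise)
  peak <- (1 - exp(-tp / rise)) * exp(-tp / decay)
  ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay) / peak)
}

# a small rigid-motion video fixture shared by tracking tests
rigid_video <- function(disp = c(0, 1, 2, 1, 0, 0.5, 1.5, 2.5, 1.2, 0),
                        seed = 3, direction_deg = 0) {
  tr <- displacement_trace(seq_along(disp) / 10 - 0.1, disp)
  synth_video(video_synthesis_spec(tr, size = c(96, 96),
                                   direction_deg = direction_deg,
                                   seed = seed))
}
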