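# myopacer

Quantifying how faithfully cultured skeletal-muscle cells follow a
periodic stimulus — optical pacing through an intramembrane molecular
photoswitch, or electrical pacing through bath electrodes.

Differentiated C2C12 myotubes have negligible spontaneous activity, so
every contraction in a paced recording can be attributed to the drive.
That makes entrainment measurable: track a region of interest through the
video, read off the contraction peaks, compare their rhythm and timing
with the pulse train. `myopacer` is an R implementation of that analysis
chain for experimenters working with paced contractile cultures:

* **Tracking** — sparse Kanade–Lucas–Tomasi-style tracking of
  minimum-eigenvalue corner features inside a user ROI (sub-pixel,
  pyramidal, with forward–backward rejection), yielding the mean
  displacement *d(t)* of the ROI from its resting position, with an
  independent phase-correlation oracle for validation.
* **Contraction detection** — peak detection on *d(t)* with amplitude,
  robust-prominence and minimum-distance rules; the beating period
  *T* = mean inter-peak interval and mean contraction frequency
  *f* = 1/*T*.
* **Behaviour classification** — greedy matching of contractions to
  pulse onsets within a response window, then one of six entrainment
  classes per cell: A (perfect follower), B (delayed start), C (early
  stop), D (both), E (transient freezing), F (random).
* **Population statistics** — mean ± sd (and SEM) cohort frequency,
  fraction of cells within 10% of the pacing target, SEM-based
  histogram bins, √N % count errors, activation dose–response curves
  and equal-activation pairing of voltage with light power density.
* **Energy models** — areal absorbed energy per pulse:
  optical *E* = (*I*·Δt)·σ*N*/*A*<sub>cell</sub> in the optically thin
  limit; electrical *E* = (*V*/*d*)²/ρ·Δt·*h* for a uniform field in a
  resistive cell layer.
* **Synthetic data** — seeded generators for ground-truth displacement
  traces (six behaviour archetypes, latency jitter, missed pulses,
  drift, sensor noise), textured videos with commanded sub-pixel motion,
  labelled populations and two-channel stained-nuclei images, so the
  entire pipeline is testable without microscopy data.

## Worked example

Pace a synthetic cell at 0.5 Hz (15 pulses of 200 ms in a 30 s train,
starting 20 s into the recording) and analyse it end to end:

```r
library(myopacer)

protocol <- stimulus_protocol(0.5, "optical", amplitude = 42)
protocol
#> <stimulus_protocol> optical, 0.5 Hz, pulse 200 ms, train 30 s starting at 20 s, amplitude 42 mW/mm^2

gen    <- synth_trace(trace_synthesis_spec("A", protocol, seed = 42))
trace  <- baseline_correct(gen$trace, protocol$train_start)
events <- detect_contractions(trace, default_peak_params(protocol))
events
#> <contraction_events> 15 peaks, mean period 2.001 s

mean_frequency(events)
#> [1] 0.4998232

tab <- match_events(events, protocol)
tab
#> <pulse_response_table> 15/15 pulses matched (100%), first 0, last 14, max gap 0
classify(tab, default_behaviour_params(protocol))
#> [1] "A"
```

All 15 pulses elicited a matched contraction with no internal gaps, so
the cell is a class-A perfect follower beating at 0.500 Hz — the pacing
frequency. A mixed cohort aggregates the same way:

```r
pop <- synth_population(c(A = 0.7, E = 0.2, F = 0.1), n = 40,
                        base_spec = trace_synthesis_spec(protocol = protocol),
                        seed = 7)
# per cell: baseline_correct |> detect_contractions |> mean_frequency,
# then summarize_population(freqs, target = 0.5):
#> <population_summary> n = 40, mean 0.426 +/- 0.132 (sd) Hz, sem 0.021 Hz
#>   70% at target 0.5 Hz, bin width 0.02 Hz, count error sqrt(N) = 6.3%
```

Freezing and erratic cells drag the cohort mean below the drive (0.426
vs 0.5 Hz) while 70% of cells still sit within 10% of the target —
the characteristic signature of an imperfectly entrained population.

`run_pipeline()` wraps the same chain (including tracking, when cells
arrive as video + ROI rather than as traces) with per-cell error
capture, CSV/JSON outputs and a reproducibility manifest.

## The analysis scripts

Numbered drivers under `analysis/` replay the full study-shaped
analysis on synthetic cohorts with the published sizes and write their
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_cohorts.R` | six labelled cohorts (optical/electrical × 0.5/1/2 Hz; n = 87/114/41/51/50/32) |
| `02_tracking_validation.R` | tracker vs ground truth and phase-correlation oracle on rendered videos |
| `03_contraction_frequency.R` | per-cohort mean ± sd frequency, at-target fractions, SEM-binned histograms |
| `04_behaviour_classification.R` | six-class distributions with √N % errors; classifier vs generator labels |
| `05_energetics.R` | single-pulse energy budgets, energy trend lines, equal-activation dose pairing |
| `06_morphometry.R` | nucleus counting, viability fractions, fusion index, orientation statistics |

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

## The vignette

`vignettes/contraction-analysis.Rmd` documents the model and its
assumptions: every tunable parameter with its default and rationale, the
noise-estimation details, the classification thresholds and their
precedence, the energy-model closure constants, what the synthetic
generator does and does not emulate, and the known limitations.
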