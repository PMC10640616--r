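Package: myopacer
Title: Quantifying Light- and Field-Paced Skeletal Muscle Cell Contraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for contraction kinetics of cultured myotubes
    paced by optical (membrane photoswitch) or electrical stimulation.
    Reconstructs sub-pixel ROI displacement traces from time-lapse microscopy
    video with a sparse Kanade-Lucas-Tomasi style tracker, detects contraction
    peaks and estimates beating frequency, matches contractions to the stimulus
    pulse train and classifies each cell into one of six entrainment behaviour
    categories, aggregates population statistics (mean frequency, fraction at
    the pacing target, activation dose-response curves, sqrt(N) percent count
    errors), and evaluates closed-form absorbed-energy models for optical and
    electrical stimulation. A synthetic-data generator produces ground-truth
    displacement traces, textured videos, behaviour populations and stained
    nuclei images so the whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
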