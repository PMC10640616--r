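#' Read a frame stack from disk
#'
#' Accepts a multi-page grayscale TIFF or a directory of same-shape
#' PNG/TIFF frames read in lexicographic order. Integer 8/16-bit and float
#' intensities are accepted and converted to doubles.
#'
#' @param path TIFF file or directory of frames.
#' @param frame_interval Seconds per frame (required; acquisition metadata
#'   is not parsed).
#' @param pixel_size Optional micrometres per pixel.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, frame_interval, pixel_size = NULL) {
  if (missing(frame_interval)) stop("frame_interval must be supplied")
  to_gray <- function(a) {
    if (length(dim(a)) == 3) a <- a[, , 1]
    matrix(as.numeric(a), nrow(a), ncol(a))
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) < 2) stop("directory holds fewer than 2 frames")
    frames <- lapply(files, function(f) {
      if (grepl("\\.png$", f, ignore.case = TRUE)) {
        to_gray(png::readPNG(f))
      } else {
        to_gray(tiff::readTIFF(f))
      }
    })
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- lapply(pages, to_gray)
  } else {
    stop("path does not exist: ", path)
  }
  dims <- lapply(frames, dim)
  if (length(unique(dims)) != 1) {
    stop("frames have mixed shapes; refusing to build a partial stack")
  }
  frame_stack(frames, frame_interval = frame_interval,
              pixel_size = pixel_size)
}

#' Write a frame stack as a multi-page grayscale TIFF
#'
#' Intensities are rescaled to `[0, 1]` over the whole stack before
#' writing.
#'
#' @param stack A [frame_stack()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  hi <- max(vapply(stack$frames, max, numeric(1)))
  lo <- min(vapply(stack$frames, min, numeric(1)))
  rng <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF(lapply(stack$frames, function(f) (f - lo) / rng), path)
  invisible(path)
}

#' Write / read a displacement trace as CSV
#'
#' Column layout: `time_s, displacement, units, n_points_alive`.
#'
#' @param trace A [displacement_trace()].
#' @param path CSV file path.
#' @return `write_trace_csv`: `path` invisibly; `read_trace_csv`: a
#'   [displacement_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  displacement_trace(d$time_s, d$displacement, d$n_points_alive,
                     units = d$units[1])
}

#' Write / read contraction events as CSV (`peak_time_s, amplitude`)
#'
#' @param events A [contraction_events()].
#' @param path CSV file path.
#' @return `write_events_csv`: `path` invisibly; `read_events_csv`: a
#'   [contraction_events()].
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  d <- utils::read.csv(path)
  contraction_events(d$peak_time_s, d$amplitude)
}

#' Default analysis configuration
#'
#' Nested defaults for every pipeline stage, serializable to JSON. Keys
#' carry their unit in the name. `analysis_config()` validates overrides
#' against the known key set and rejects unknown keys.
#'
#' @param ... Named sections overriding defaults, e.g.
#'   `peaks = list(prominence_k = 5)`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    protocol = list(frequency_hz = 1, modality = "optical",
                    pulse_width_s = NULL, train_start_s = 20,
                    train_duration_s = 30, amplitude = 42),
    tracking = list(n_rows = 2, n_cols = 2, max_features_per_cell = 10,
                    min_features = 5, window_px = 15, pyramid_levels = 3,
                    max_iter = 30, eps_px = 0.01, fb_max_px = 1.0,
                    min_alive_fraction = 0.5),
    peaks = list(min_distance_factor = 0.5, min_amplitude = 0,
                 prominence_k = 4, smoothing_frames = 3),
    behaviour = list(response_window_factor = 1, start_delay_pulses = 2,
                     early_stop_pulses = 2, freeze_gap_pulses = 2,
                     min_matched_fraction = 0.5),
    population = list(target_tolerance = 0.10),
    energetics = list(cross_section_cm2 = 2e-15, molecules_per_cell = 1e5,
                      cell_footprint_cm2 = 1e-5, layer_height_m = 1e-5,
                      electrode_gap_m = 7e-3, resistivity_ohm_m = 5.8e-1),
    synthesis = list(fps = 10, tail_s = 10, rise_time_s = 0.05,
                     decay_time_s = 0.15, amplitude_px = 3,
                     latency_mean_s = 0.1, latency_jitter_sd_s = 0.05),
    seed = 1
  )
  over <- list(...)
  for (sec in names(over)) {
    if (!sec %in% names(defaults)) stop("unknown config section: ", sec)
    if (sec == "seed") { defaults$seed <- over$seed; next }
    for (key in names(over[[sec]])) {
      if (!key %in% names(defaults[[sec]])) {
        stop(sprintf("unknown config key: %s.%s", sec, key))
      }
      defaults[[sec]][key] <- over[[sec]][key]
    }
  }
  structure(defaults, class = "analysis_config")
}

config_protocol <- function(config) {
  p <- config$protocol
  stimulus_protocol(p$frequency_hz, p$modality,
                    pulse_width = p$pulse_width_s,
                    train_start = p$train_start_s,
                    train_duration = p$train_duration_s,
                    amplitude = p$amplitude)
}

#' Run manifest
#'
#' Snapshot sufficient to reproduce a run: configuration, input digests,
#' package version, timestamp and seed.
#'
#' @param config An [analysis_config()].
#' @param inputs Character vector of input file paths (digested with MD5)
#'   or `NULL` for fully synthetic runs.
#' @param seed Integer seed of the run.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, inputs = NULL, seed = config$seed) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  structure(
    list(config = unclass(config),
         input_md5 = digests,
         package_version = as.character(utils::packageVersion("myopacer")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed),
    class = "run_manifest"
  )
}

#' Write a manifest, summary or config as JSON
#'
#' @param x A list-like object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_out <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the end-to-end contraction analysis
#'
#' For each cell (a displacement trace, or a video plus ROI): baseline
#' correction, contraction detection, mean-frequency estimation,
#' pulse matching and behaviour classification; then population
#' aggregation over cells with a defined frequency. Per-cell failures are
#' recorded without aborting the batch; the call errors only if every cell
#' fails.
#'
#' @param cells A list; each element is either a [displacement_trace()] or
#'   a list with elements `stack` (a [frame_stack()]) and `roi` (a
#'   [roi()]).
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, per-cell trace/event
#'   CSVs, the class table, the population summary JSON and the manifest
#'   are written there.
#' @return A list of class `pipeline_result` with `per_cell` (data frame
#'   `cell_id`, `class`, `frequency_hz`, `n_events`, `matched_fraction`,
#'   `first_matched`, `last_matched`, `max_gap`, `error`), `summary` (a
#'   `population_summary` or `NULL`), `events` (per-cell
#'   [contraction_events()]), and `manifest`.
#' @export
run_pipeline <- function(cells, config = analysis_config(),
                         out_dir = NULL) {
  stopifnot(is.list(cells), length(cells) >= 1)
  protocol <- config_protocol(config)
  pk <- peak_params(
    min_distance_s = config$peaks$min_distance_factor *
      protocol_period(protocol),
    min_amplitude = config$peaks$min_amplitude,
    prominence_k = config$peaks$prominence_k,
    smoothing_frames = config$peaks$smoothing_frames,
    noise_window_s = if (protocol$train_start > 0) protocol$train_start
  )
  bp <- behaviour_params(
    response_window = config$behaviour$response_window_factor *
      protocol_period(protocol),
    start_delay_pulses = config$behaviour$start_delay_pulses,
    early_stop_pulses = config$behaviour$early_stop_pulses,
    freeze_gap_pulses = config$behaviour$freeze_gap_pulses,
    min_matched_fraction = config$behaviour$min_matched_fraction
  )
  tcfg <- tracking_config(
    n_rows = config$tracking$n_rows, n_cols = config$tracking$n_cols,
    max_features_per_cell = config$tracking$max_features_per_cell,
    min_features = config$tracking$min_features,
    window = config$tracking$window_px,
    pyramid_levels = config$tracking$pyramid_levels,
    max_iter = config$tracking$max_iter, eps = config$tracking$eps_px,
    fb_max_px = config$tracking$fb_max_px,
    min_alive_fraction = config$tracking$min_alive_fraction
  )
  n <- length(cells)
  res <- data.frame(cell_id = seq_len(n), class = NA_character_,
                    frequency_hz = NA_real_, n_events = NA_integer_,
                    matched_fraction = NA_real_,
                    first_matched = NA_integer_,
                    last_matched = NA_integer_, max_gap = NA_integer_,
                    error = NA_character_)
  all_events <- vector("list", n)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    r <- tryCatch({
      cell <- cells[[i]]
      trace <- if (inherits(cell, "displacement_trace")) {
        cell
      } else {
        track_displacement(cell$stack, cell$roi, tcfg)
      }
      trace <- baseline_correct(trace, protocol$train_start)
      ev <- detect_contractions(trace, pk)
      tab <- match_events(ev, protocol, bp$response_window)
      cls <- classify(tab, bp)
      freq <- if (length(ev$peak_times) >= 2) mean_frequency(ev) else NA_real_
      list(trace = trace, events = ev, class = cls, freq = freq,
           tab = tab)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      res$error[i] <- conditionMessage(r)
      next
    }
    traces[[i]] <- r$trace
    all_events[[i]] <- r$events
    res$class[i] <- r$class
    res$frequency_hz[i] <- r$freq
    res$n_events[i] <- length(r$events$peak_times)
    res$matched_fraction[i] <- r$tab$matched_fraction
    res$first_matched[i] <- r$tab$first_matched_index
    res$last_matched[i] <- r$tab$last_matched_index
    res$max_gap[i] <- r$tab$max_internal_gap
  }
  if (all(!is.na(res$error))) {
    stop("all cells failed: first error: ", res$error[1])
  }
  freqs <- res$frequency_hz[!is.na(res$frequency_hz)]
  summary <- if (length(freqs) >= 1) {
    summarize_population(freqs, target = protocol$frequency,
                         tolerance = config$population$target_tolerance)
  }
  manifest <- run_manifest(config, inputs = NULL, seed = config$seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      if (!is.null(traces[[i]])) {
        write_trace_csv(traces[[i]],
                        file.path(out_dir, sprintf("trace_%03d.csv", i)))
        write_events_csv(all_events[[i]],
                         file.path(out_dir, sprintf("events_%03d.csv", i)))
      }
    }
    utils::write.csv(
      res[, c("cell_id", "class", "matched_fraction", "first_matched",
              "last_matched", "max_gap")],
      file.path(out_dir, "classes.csv"), row.names = FALSE
    )
    if (!is.null(summary)) {
      write_json_out(
        list(n = summary$n, mean_hz = summary$mean, sd_hz = summary$sd,
             sem_hz = summary$sem,
             fraction_at_target = summary$fraction_at_target,
             bins = summary$breaks, counts = summary$counts),
        file.path(out_dir, "population.json")
      )
    }
    write_json_out(manifest, file.path(out_dir, "manifest.json"))
  }
  structure(
    list(per_cell = res, summary = summary, events = all_events,
         manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  ok <- sum(is.na(x$per_cell$error))
  cat(sprintf("<pipeline_result> %d/%d cells analysed\n", ok,
              nrow(x$per_cell)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
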