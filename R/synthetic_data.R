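# Run code under a fixed seed without clobbering the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic displacement trace
#'
#' Describes one simulated cell: which behaviour class it enacts, the
#' pacing protocol, the contraction transient shape and the degradations
#' (latency jitter, missed pulses, baseline drift, sensor noise) that
#' emulate real recordings. Class-structure fields are only accepted for
#' the classes they belong to: `start_delay_pulses` for B/D,
#' `early_stop_pulses` for C/D, `freeze_start_pulse`/`freeze_length_pulses`
#' for E.
#'
#' The contraction transient is an asymmetric double exponential
#' `(1 - exp(-t/rise)) * exp(-t/decay)`, peak-normalized, mirroring the
#' fast-rise slow-decay shape of measured contraction paths.
#'
#' @param behaviour_class One of `"A"`..`"F"`.
#' @param protocol A [stimulus_protocol()].
#' @param latency_mean Mean contraction latency after a pulse onset, s.
#' @param latency_jitter_sd Latency jitter SD, s.
#' @param miss_probability Probability of skipping an otherwise scheduled
#'   pulse response. Defaults to 0, except 0.7 for class F.
#' @param rise_time,decay_time Transient shape constants, s
#'   (`rise_time < decay_time`).
#' @param amplitude Transient peak amplitude, px (0 gives a flat trace).
#' @param start_delay_pulses Pulses skipped at the train start (B/D).
#' @param early_stop_pulses Pulses skipped at the train end (C/D).
#' @param freeze_start_pulse,freeze_length_pulses Freezing window (E),
#'   0-based start pulse and length in pulses.
#' @param spontaneous_rate Poisson rate of stimulus-unrelated events per
#'   second, applied over the whole recording (class F default 0.15, else
#'   0).
#' @param noise_sd Gaussian sensor noise SD, px (default 5% of amplitude).
#' @param drift_slope Linear baseline drift, px/s.
#' @param fps Trace sampling rate, frames/s.
#' @param tail_s Quiet recording time after the train end, s.
#' @param seed Integer seed fixing all randomness; `NULL` draws from the
#'   current RNG state (used by [synth_population()]).
#' @return A list of class `trace_synthesis_spec`.
#' @export
trace_synthesis_spec <- function(behaviour_class = "A",
                                 protocol = stimulus_protocol(1, "optical"),
                                 latency_mean = 0.1,
                                 latency_jitter_sd = 0.05,
                                 miss_probability = NULL,
                                 rise_time = 0.05,
                                 decay_time = 0.15,
                                 amplitude = 3,
                                 start_delay_pulses = NULL,
                                 early_stop_pulses = NULL,
                                 freeze_start_pulse = NULL,
                                 freeze_length_pulses = NULL,
                                 spontaneous_rate = NULL,
                                 noise_sd = NULL,
                                 drift_slope = 0,
                                 fps = 10,
                                 tail_s = 10,
                                 seed = NULL) {
  stopifnot(behaviour_class %in% c("A", "B", "C", "D", "E", "F"),
            inherits(protocol, "stimulus_protocol"),
            rise_time > 0, decay_time > rise_time, amplitude >= 0,
            latency_jitter_sd >= 0, fps > 0, tail_s >= 0)
  cls <- behaviour_class
  if (!is.null(start_delay_pulses) && !cls %in% c("B", "D")) {
    stop("start_delay_pulses is only meaningful for classes B and D")
  }
  if (!is.null(early_stop_pulses) && !cls %in% c("C", "D")) {
    stop("early_stop_pulses is only meaningful for classes C and D")
  }
  if (!is.null(freeze_start_pulse) && cls != "E") {
    stop("a freezing window is only meaningful for class E")
  }
  np <- length(pulse_onsets(protocol))
  # archetype defaults: clearly beyond the classification thresholds
  # (delay/stop of several pulses, freezes of >= 3 pulses) while keeping
  # the matched fraction of B/C/D cells above the class-F cutoff
  if (cls %in% c("B", "D") && is.null(start_delay_pulses)) {
    start_delay_pulses <- if (cls == "D") max(3, ceiling(np / 8)) else
      max(4, ceiling(np / 6))
  }
  if (cls %in% c("C", "D") && is.null(early_stop_pulses)) {
    early_stop_pulses <- if (cls == "D") max(3, ceiling(np / 8)) else
      max(4, ceiling(np / 6))
  }
  if (cls == "E") {
    if (is.null(freeze_start_pulse)) freeze_start_pulse <- floor(np / 3)
    if (is.null(freeze_length_pulses)) {
      freeze_length_pulses <- max(3, ceiling(np / 8))
    }
  }
  if (is.null(miss_probability)) {
    miss_probability <- if (cls == "F") 0.8 else 0
  }
  if (is.null(spontaneous_rate)) {
    spontaneous_rate <- if (cls == "F") 0.08 else 0
  }
  if (is.null(noise_sd)) noise_sd <- 0.05 * amplitude
  stopifnot(miss_probability >= 0, miss_probability <= 1,
            spontaneous_rate >= 0, noise_sd >= 0)
  structure(
    list(behaviour_class = cls, protocol = protocol,
         latency_mean = latency_mean, latency_jitter_sd = latency_jitter_sd,
         miss_probability = miss_probability, rise_time = rise_time,
         decay_time = decay_time, amplitude = amplitude,
         start_delay_pulses = start_delay_pulses,
         early_stop_pulses = early_stop_pulses,
         freeze_start_pulse = freeze_start_pulse,
         freeze_length_pulses = freeze_length_pulses,
         spontaneous_rate = spontaneous_rate, noise_sd = noise_sd,
         drift_slope = drift_slope, fps = fps, tail_s = tail_s,
         seed = seed),
    class = "trace_synthesis_spec"
  )
}

# time from transient onset to its peak, and the peak value of the
# unnormalized double exponential
transient_peak_time <- function(rise, decay) rise * log(1 + decay / rise)

transient_shape <- function(t, rise, decay) {
  tp <- transient_peak_time(rise, decay)
  peak <- (1 - exp(-tp / rise)) * exp(-tp / decay)
  ifelse(t < 0, 0, (1 - exp(-t / rise)) * exp(-t / decay) / peak)
}

#' Generate a ground-truth displacement trace
#'
#' Simulates the displacement trace of one cell under the spec's protocol
#' and behaviour class: each non-skipped pulse emits a peak-normalized
#' double-exponential transient at `onset + latency` (latency drawn from a
#' truncated normal), transients and drift are summed into the axial
#' displacement, Gaussian sensor noise perturbs both coordinates of the
#' tracked position, and the trace is the resulting Euclidean magnitude
#' with frame 0 anchored at rest.
#'
#' @param spec A [trace_synthesis_spec()].
#' @return List with elements `trace` (a [displacement_trace()]),
#'   `event_times` (true transient peak times, s), `class` (the intended
#'   behaviour label) and `spec`.
#' @export
synth_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_synthesis_spec"))
  with_seed_(spec$seed, {
    pr <- spec$protocol
    onsets <- pulse_onsets(pr)
    np <- length(onsets)
    respond <- rep(TRUE, np)
    cls <- spec$behaviour_class
    if (cls %in% c("B", "D")) {
      respond[seq_len(min(spec$start_delay_pulses, np))] <- FALSE
    }
    if (cls %in% c("C", "D")) {
      k <- min(spec$early_stop_pulses, np)
      respond[seq.int(np - k + 1, np)] <- FALSE
    }
    if (cls == "E") {
      i0 <- spec$freeze_start_pulse + 1
      i1 <- min(i0 + spec$freeze_length_pulses - 1, np)
      respond[i0:i1] <- FALSE
    }
    respond <- respond & (stats::runif(np) >= spec$miss_probability)
    latencies <- pmax(stats::rnorm(np, spec$latency_mean,
                                   spec$latency_jitter_sd), 0)
    starts <- onsets[respond] + latencies[respond]
    total_s <- pr$train_start + pr$train_duration + spec$tail_s
    if (spec$spontaneous_rate > 0) {
      n_sp <- stats::rpois(1, spec$spontaneous_rate * total_s)
      starts <- sort(c(starts, stats::runif(n_sp, 0, total_s)))
    }
    times <- seq(0, total_s, by = 1 / spec$fps)
    s <- numeric(length(times))
    for (t0 in starts) {
      s <- s + spec$amplitude *
        transient_shape(times - t0, spec$rise_time, spec$decay_time)
    }
    s <- s + spec$drift_slope * times
    # the trace is the magnitude of a noisy 2-D tracked position: Gaussian
    # sensor noise perturbs each coordinate, so the resting baseline is a
    # strictly positive Rayleigh floor, as in real tracker output
    nx <- stats::rnorm(length(times), 0, spec$noise_sd)
    ny <- stats::rnorm(length(times), 0, spec$noise_sd)
    y <- sqrt((s + nx)^2 + ny^2)
    y[1] <- 0
    tp <- transient_peak_time(spec$rise_time, spec$decay_time)
    list(trace = displacement_trace(times, y, units = "px"),
         event_times = starts + tp,
         class = cls,
         spec = spec)
  })
}

#' Specification of a synthetic contraction video
#'
#' @param trace Ground-truth [displacement_trace()] driving the motion
#'   (pixels).
#' @param size Frame size `c(height, width)` in px.
#' @param texture_corr_px Correlation length of the band-limited random
#'   texture, px (Gaussian smoothing sigma).
#' @param direction_deg Motion direction, degrees (0 = +x).
#' @param noise_scale Scale of the Poisson-like sensor noise (SD =
#'   `noise_scale * sqrt(intensity)`).
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `video_synthesis_spec`.
#' @export
video_synthesis_spec <- function(trace,
                                 size = c(96, 96),
                                 texture_corr_px = 3,
                                 direction_deg = 0,
                                 noise_scale = 0.01,
                                 seed = 1) {
  stopifnot(inherits(trace, "displacement_trace"), length(size) == 2,
            texture_corr_px > 0, noise_scale >= 0)
  if (max(trace$displacement) > 0.1 * min(size)) {
    stop("displacement exceeds 10% of the frame size guard band")
  }
  structure(
    list(trace = trace, size = as.integer(size),
         texture_corr_px = texture_corr_px,
         direction_deg = direction_deg, noise_scale = noise_scale,
         seed = seed),
    class = "video_synthesis_spec"
  )
}

# sample `tex` at integer output grid shifted by (dx, dy), bilinearly
shift_sample <- function(tex, dx, dy, h, w, pad) {
  xs <- seq_len(w) + pad - dx
  ys <- seq_len(h) + pad - dy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  rr <- rep(y0, times = w); cc <- rep(x0, each = h)
  wfy <- rep(fy, times = w); wfx <- rep(fx, each = h)
  v <- (1 - wfy) * (1 - wfx) * tex[cbind(rr, cc)] +
       (1 - wfy) * wfx       * tex[cbind(rr, cc + 1L)] +
       wfy       * (1 - wfx) * tex[cbind(rr + 1L, cc)] +
       wfy       * wfx       * tex[cbind(rr + 1L, cc + 1L)]
  matrix(v, h, w)
}

#' Render a synthetic contraction video
#'
#' Renders a band-limited random texture (a textured cell body) whose
#' content translates rigidly along `direction_deg` by the ground-truth
#' displacement of each frame, with sub-pixel bilinear interpolation and
#' Poisson-like sensor noise. Frame 0 is the resting frame.
#'
#' @param spec A [video_synthesis_spec()].
#' @return List with elements `stack` (a [frame_stack()]) and `trace` (the
#'   ground-truth [displacement_trace()]).
#' @export
synth_video <- function(spec) {
  stopifnot(inherits(spec, "video_synthesis_spec"))
  with_seed_(spec$seed, {
    h <- spec$size[1]; w <- spec$size[2]
    pad <- ceiling(max(spec$trace$displacement)) + 3L
    tex <- matrix(stats::rnorm((h + 2 * pad) * (w + 2 * pad)),
                  h + 2 * pad, w + 2 * pad)
    tex <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(tex), sigma = spec$texture_corr_px)
    ))
    tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 0.8 + 0.2
    ux <- cos(spec$direction_deg * pi / 180)
    uy <- sin(spec$direction_deg * pi / 180)
    dt <- trace_interval(spec$trace)
    frames <- lapply(seq_along(spec$trace$times), function(k) {
      d <- spec$trace$displacement[k]
      f <- shift_sample(tex, d * ux, d * uy, h, w, pad)
      if (spec$noise_scale > 0) {
        f <- f + stats::rnorm(length(f), 0, spec$noise_scale * sqrt(f))
      }
      pmax(f, 0)
    })
    list(stack = frame_stack(frames, frame_interval = dt),
         trace = spec$trace)
  })
}

#' Generate a labelled population of synthetic cells
#'
#' Draws `n` behaviour classes i.i.d. from `class_probabilities`, perturbs
#' the base trace spec per cell (log-normal amplitude spread, jittered mean
#' latency) and synthesizes each trace. All randomness is fixed by `seed`.
#'
#' @param class_probabilities Named numeric vector of class fractions
#'   (names among `"A"`..`"F"`, summing to 1).
#' @param n Number of cells.
#' @param base_spec Template [trace_synthesis_spec()]; its class and seed
#'   fields are overridden per cell.
#' @param seed Integer seed.
#' @param amplitude_cv Per-cell log-normal coefficient of variation of the
#'   transient amplitude.
#' @return List with `cells` (per-cell lists as returned by
#'   [synth_trace()]) and `labels` (data frame `cell_id`, `true_class`).
#' @export
synth_population <- function(class_probabilities, n,
                             base_spec = trace_synthesis_spec(),
                             seed = 1,
                             amplitude_cv = 0.2) {
  stopifnot(n >= 1, all(names(class_probabilities) %in%
                          c("A", "B", "C", "D", "E", "F")))
  p <- as.numeric(class_probabilities)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("class probabilities must be non-negative and sum to 1")
  }
  with_seed_(seed, {
    draws <- sample(names(class_probabilities), n, replace = TRUE, prob = p)
    cells <- lapply(seq_len(n), function(i) {
      sp <- base_spec
      sp$behaviour_class <- draws[i]
      # class-structure fields follow the drawn class, not the template
      sp$start_delay_pulses <- NULL
      sp$early_stop_pulses <- NULL
      sp$freeze_start_pulse <- NULL
      sp$freeze_length_pulses <- NULL
      sp$seed <- NULL
      sp <- do.call(trace_synthesis_spec, c(
        list(behaviour_class = draws[i], protocol = sp$protocol),
        sp[c("latency_mean", "latency_jitter_sd", "rise_time", "decay_time",
             "drift_slope", "fps", "tail_s")]
      ))
      sp$amplitude <- base_spec$amplitude *
        stats::rlnorm(1, -amplitude_cv^2 / 2, amplitude_cv)
      sp$latency_mean <- max(0.02, stats::rnorm(1, base_spec$latency_mean,
                                                0.02))
      sp$noise_sd <- 0.05 * sp$amplitude
      synth_trace(sp)
    })
    list(cells = cells,
         labels = data.frame(cell_id = seq_len(n), true_class = draws))
  })
}

#' Render a synthetic two-channel stained-nuclei image
#'
#' Places `n_total` non-overlapping Gaussian spots (nuclei); all appear in
#' the "all" channel (Hoechst-like) and a random subset of `n_dead` also in
#' the "dead" channel (propidium-iodide-like). Placement is by rejection
#' sampling; if the requested density cannot be placed the call errors
#' without partial output.
#'
#' @param n_total Total nuclei.
#' @param n_dead Dead nuclei (`<= n_total`).
#' @param size Image size `c(height, width)` px.
#' @param spot_sigma Gaussian spot sigma, px.
#' @param min_spacing Minimum centre spacing, px (default `6 * spot_sigma`).
#' @param seed Integer seed.
#' @return List with `channels` (list of matrices `all`, `dead`) and
#'   `truth` (data frame `x_px`, `y_px`, `dead`).
#' @export
synth_nuclei_image <- function(n_total, n_dead,
                               size = c(256, 256),
                               spot_sigma = 2.5,
                               min_spacing = 6 * spot_sigma,
                               seed = 1) {
  stopifnot(n_total >= 1, n_dead >= 0, n_dead <= n_total)
  with_seed_(seed, {
    h <- size[1]; w <- size[2]
    margin <- ceiling(4 * spot_sigma)
    xs <- numeric(0); ys <- numeric(0)
    max_tries <- 200 * n_total
    tries <- 0
    while (length(xs) < n_total) {
      tries <- tries + 1
      if (tries > max_tries) {
        stop("cannot place the requested nucleus density without overlap")
      }
      x <- stats::runif(1, margin, w - 1 - margin)
      y <- stats::runif(1, margin, h - 1 - margin)
      if (length(xs) > 0 &&
          min((xs - x)^2 + (ys - y)^2) < min_spacing^2) next
      xs <- c(xs, x); ys <- c(ys, y)
    }
    dead <- rep(FALSE, n_total)
    if (n_dead > 0) dead[sample.int(n_total, n_dead)] <- TRUE
    render <- function(sel) {
      img <- matrix(0, h, w)
      half <- ceiling(4 * spot_sigma)
      for (i in which(sel)) {
        rr <- (round(ys[i]) - half):(round(ys[i]) + half)
        cc <- (round(xs[i]) - half):(round(xs[i]) + half)
        gy <- exp(-((rr - ys[i])^2) / (2 * spot_sigma^2))
        gx <- exp(-((cc - xs[i])^2) / (2 * spot_sigma^2))
        img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + outer(gy, gx)
      }
      img
    }
    list(
      channels = list(all = render(rep(TRUE, n_total)), dead = render(dead)),
      truth = data.frame(x_px = xs, y_px = ys, dead = dead)
    )
  })
}
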