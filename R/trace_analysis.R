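#' Peak-detection parameters
#'
#' Rules used to accept a local maximum of the displacement trace as a
#' contraction: it must exceed `min_amplitude`, rise at least
#' `prominence_k` robust noise standard deviations above its surrounding
#' baseline, and lie at least `min_distance_s` from any stronger accepted
#' peak. The robust noise SD is estimated as `1.4826 * MAD(diff(y)) /
#' sqrt(2)` over the pre-event part of the trace.
#'
#' @param min_distance_s Minimum spacing between two contractions, seconds.
#'   A natural choice under periodic pacing is half the stimulation period
#'   (see [default_peak_params()]).
#' @param min_amplitude Minimum trace value at the peak (trace units).
#'   Default 0: the prominence rule does the discriminating.
#' @param prominence_k Required prominence in units of the robust noise SD.
#' @param smoothing_frames Width (frames) of the centred moving average
#'   applied before detection; 1 disables smoothing.
#' @param noise_window_s Portion of the trace (from its start) used for the
#'   noise estimate; `NULL` uses the whole trace.
#' @return A list of class `peak_params`.
#' @export
peak_params <- function(min_distance_s,
                        min_amplitude = 0,
                        prominence_k = 4,
                        smoothing_frames = 3,
                        noise_window_s = NULL) {
  stopifnot(min_distance_s > 0, prominence_k >= 0, smoothing_frames >= 1)
  structure(
    list(min_distance_s = min_distance_s, min_amplitude = min_amplitude,
         prominence_k = prominence_k, smoothing_frames = smoothing_frames,
         noise_window_s = noise_window_s),
    class = "peak_params"
  )
}

#' Default peak parameters for a pacing protocol
#'
#' Sets the minimum inter-peak distance to half the stimulation period so
#' that every paced contraction is resolvable up to the pacing rate, and
#' the noise window to the pre-stimulus baseline.
#'
#' @param protocol A [stimulus_protocol()].
#' @inheritParams peak_params
#' @return A [peak_params()] object.
#' @export
default_peak_params <- function(protocol, prominence_k = 4,
                                smoothing_frames = 3) {
  peak_params(min_distance_s = 0.5 * protocol_period(protocol),
              prominence_k = prominence_k,
              smoothing_frames = smoothing_frames,
              noise_window_s = if (protocol$train_start > 0) {
                protocol$train_start
              } else {
                NULL
              })
}

#' Contraction events
#'
#' @param peak_times Strictly increasing contraction peak times, seconds.
#' @param peak_amplitudes Trace value at each peak.
#' @return Object of class `contraction_events` with a `periods` field
#'   holding successive peak-time differences.
#' @export
contraction_events <- function(peak_times, peak_amplitudes) {
  stopifnot(length(peak_times) == length(peak_amplitudes))
  if (length(peak_times) > 1 && any(diff(peak_times) <= 0)) {
    stop("peak_times must be strictly increasing")
  }
  structure(
    list(peak_times = as.numeric(peak_times),
         peak_amplitudes = as.numeric(peak_amplitudes),
         periods = if (length(peak_times) > 1) diff(peak_times) else numeric(0)),
    class = "contraction_events"
  )
}

#' @export
print.contraction_events <- function(x, ...) {
  cat(sprintf("<contraction_events> %d peaks", length(x$peak_times)))
  if (length(x$periods) > 0) {
    cat(sprintf(", mean period %.3f s", mean(x$periods)))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.contraction_events <- function(x, ...) {
  data.frame(peak_time_s = x$peak_times, amplitude = x$peak_amplitudes)
}

#' Remove baseline offset and slow drift from a trace
#'
#' Subtracts the median of the pre-stimulus segment and, by default, a
#' linear drift fitted on that segment and extrapolated over the whole
#' recording. The result is clipped at zero and re-anchored so the first
#' frame stays the resting zero point.
#'
#' @param trace A [displacement_trace()].
#' @param pre_stimulus_end End of the quiet pre-stimulus window, seconds
#'   (exclusive); typically the train start of the protocol.
#' @param detrend Remove a linear drift fitted on the pre-stimulus segment.
#' @return A corrected [displacement_trace()].
#' @export
baseline_correct <- function(trace, pre_stimulus_end, detrend = TRUE) {
  stopifnot(inherits(trace, "displacement_trace"))
  sel <- trace$times < pre_stimulus_end
  if (!any(sel)) stop("empty pre-stimulus window")
  y <- trace$displacement
  if (detrend && sum(sel) >= 3) {
    fit <- stats::lm.fit(cbind(1, trace$times[sel]), y[sel])
    y <- y - (fit$coefficients[1] + fit$coefficients[2] * trace$times)
  } else {
    y <- y - stats::median(y[sel])
  }
  y <- pmax(y, 0)
  y[1] <- 0
  displacement_trace(trace$times, y, trace$n_points_alive, trace$units)
}

# partial-window centred moving average
moving_average <- function(y, w) {
  if (w <= 1) return(y)
  half <- (w - 1) %/% 2
  n <- length(y)
  cs <- c(0, cumsum(y))
  i0 <- pmax(seq_len(n) - half, 1)
  i1 <- pmin(seq_len(n) + half, n)
  (cs[i1 + 1] - cs[i0]) / (i1 - i0 + 1)
}

# prominence of a local maximum at index i: height above the higher of the
# two minima separating it from the nearest taller sample on each side
peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- y[i]; j <- i - 1
  lm <- Inf
  while (j >= 1 && y[j] <= y[i]) { lm <- min(lm, y[j]); j <- j - 1 }
  left_base <- if (is.finite(lm)) lm else y[i]
  rm <- Inf; j <- i + 1
  while (j <= n && y[j] <= y[i]) { rm <- min(rm, y[j]); j <- j + 1 }
  right_base <- if (is.finite(rm)) rm else y[i]
  y[i] - max(left_base, right_base)
}

#' Detect contraction events in a displacement trace
#'
#' Finds local maxima of the (optionally smoothed) trace that pass the
#' amplitude, prominence and minimum-distance rules of [peak_params()].
#' Distance violations are resolved in favour of the higher peak
#' (strongest-first suppression). Peak times are refined to sub-frame
#' precision by a parabolic fit through the three samples around each
#' maximum.
#'
#' @param trace A [displacement_trace()] with uniform sampling.
#' @param params A [peak_params()].
#' @return A [contraction_events()] object.
#' @export
detect_contractions <- function(trace, params) {
  stopifnot(inherits(trace, "displacement_trace"),
            inherits(params, "peak_params"))
  n <- length(trace$times)
  if (n < 3) stop("trace must have at least 3 samples")
  dt <- trace_interval(trace)
  y <- moving_average(trace$displacement, params$smoothing_frames)
  # noise estimated on the raw trace: 1.4826 * MAD of the first difference
  # over sqrt(2). Zero-clipped baselines censor half the noise and deflate
  # the MAD, so an upper-quantile estimator (the 84.13th percentile of the
  # first difference equals +1 SD for centred noise) guards against that.
  raw <- trace$displacement
  pre <- if (is.null(params$noise_window_s)) {
    raw
  } else {
    yy <- raw[trace$times <= trace$times[1] + params$noise_window_s]
    if (length(yy) < 3) raw else yy
  }
  d1 <- diff(pre)
  qq <- as.numeric(stats::quantile(pre, c(0.5, 0.8413)))
  noise_sd <- max(stats::mad(d1, constant = 1.4826) / sqrt(2),
                  qq[2] - qq[1])
  # candidate local maxima (left-strict, right-non-strict handles plateaus)
  i <- 2:(n - 1)
  cand <- i[y[i] > y[i - 1] & y[i] >= y[i + 1]]
  cand <- cand[y[cand] > params$min_amplitude]
  if (length(cand) > 0 && params$prominence_k > 0) {
    prom <- vapply(cand, function(k) peak_prominence(y, k), numeric(1))
    cand <- cand[prom >= params$prominence_k * noise_sd]
  }
  # strongest-first minimum-distance suppression
  if (length(cand) > 1) {
    ord <- cand[order(y[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (k in ord) {
      if (length(kept) == 0 ||
          min(abs(trace$times[kept] - trace$times[k])) >=
            params$min_distance_s - 1e-9) {
        kept <- c(kept, k)
      }
    }
    cand <- sort(kept)
  }
  if (length(cand) == 0) {
    return(contraction_events(numeric(0), numeric(0)))
  }
  # localize on the raw trace: smoothing an asymmetric (slow-decay)
  # transient biases its maximum late, so the peak sample is re-found on
  # the unsmoothed signal near each smoothed candidate before the
  # parabolic sub-frame refinement
  raw_y <- trace$displacement
  half_w <- max(1L, (params$smoothing_frames - 1L) %/% 2L)
  cand <- vapply(cand, function(k) {
    lo <- max(2L, k - half_w)
    hi <- min(n - 1L, k + half_w)
    (lo:hi)[which.max(raw_y[lo:hi])]
  }, integer(1))
  cand <- sort(unique(cand))
  times <- vapply(cand, function(k) {
    ym <- raw_y[k - 1]; y0 <- raw_y[k]; yp <- raw_y[k + 1]
    den <- ym - 2 * y0 + yp
    delta <- if (abs(den) < 1e-12) 0 else 0.5 * (ym - yp) / den
    trace$times[k] + max(min(delta, 0.5), -0.5) * dt
  }, numeric(1))
  contraction_events(times, raw_y[cand])
}

#' Mean contraction frequency
#'
#' The beating period is the mean of the inter-peak intervals; the mean
#' contraction frequency is its reciprocal. Cells with fewer than two
#' detected contractions have no defined frequency and raise an error so
#' the caller can exclude them from frequency statistics.
#'
#' @param events A [contraction_events()] with at least two peaks.
#' @return Frequency in Hz.
#' @export
mean_frequency <- function(events) {
  stopifnot(inherits(events, "contraction_events"))
  if (length(events$peak_times) < 2) {
    stop("fewer than 2 events: contraction frequency is undefined")
  }
  1 / mean(events$periods)
}
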