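#' Stimulation protocol
#'
#' Describes the periodic pulse train used to pace myotube contraction,
#' either optically (a cyan LED driving a membrane photoswitch) or
#' electrically (platinum bath electrodes). A protocol is a square pulse
#' train: pulses of width `pulse_width` (the on-time, often written
#' delta-t1) repeating at `frequency`, starting `train_start` seconds into
#' the recording and lasting `train_duration` seconds. The off-time within
#' one period (delta-t2) is `1/frequency - pulse_width`.
#'
#' Default pulse widths follow the stimulation hardware settings used for
#' paced myotube recordings: 200 ms optical pulses at 0.5 and 1 Hz, 100 ms
#' at 2 Hz, and 20 ms electrical pulses at every frequency.
#'
#' @param frequency Pulse repetition rate in Hz. Must be > 0.
#' @param modality `"optical"` or `"electrical"`.
#' @param pulse_width Pulse on-time in seconds. `NULL` picks the modality
#'   and frequency dependent default described above.
#' @param train_start Time of the first pulse onset, seconds from the start
#'   of the recording. Default 20 s (quiet baseline before pacing).
#' @param train_duration Length of the pulse train in seconds. Default 30 s.
#' @param amplitude Stimulus amplitude: power density in mW/mm^2 for optical
#'   protocols, applied voltage in V for electrical ones.
#' @param amplitude_units Unit label for `amplitude`; defaulted from the
#'   modality.
#'
#' @return An object of class `stimulus_protocol`.
#' @examples
#' p <- stimulus_protocol(1, "optical", amplitude = 42)
#' pulse_onsets(p)[1:3]   # 20, 21, 22
#' protocol_period(p)     # 1
#' @export
stimulus_protocol <- function(frequency,
                              modality = c("optical", "electrical"),
                              pulse_width = NULL,
                              train_start = 20,
                              train_duration = 30,
                              amplitude = NA_real_,
                              amplitude_units = NULL) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(frequency), length(frequency) == 1, frequency > 0)
  if (is.null(pulse_width)) {
    pulse_width <- if (modality == "electrical") {
      0.020
    } else if (frequency >= 2) {
      0.100
    } else {
      0.200
    }
  }
  if (is.null(amplitude_units)) {
    amplitude_units <- if (modality == "optical") "mW/mm^2" else "V"
  }
  stopifnot(train_start >= 0, train_duration > 0, pulse_width > 0)
  if (pulse_width >= 1 / frequency) {
    stop("pulse_width must be shorter than the stimulation period (1/frequency)")
  }
  structure(
    list(
      modality = modality,
      frequency = frequency,
      pulse_width = pulse_width,
      train_start = train_start,
      train_duration = train_duration,
      amplitude = amplitude,
      amplitude_units = amplitude_units
    ),
    class = "stimulus_protocol"
  )
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf(
    "<stimulus_protocol> %s, %g Hz, pulse %g ms, train %g s starting at %g s, amplitude %g %s\n",
    x$modality, x$frequency, 1000 * x$pulse_width, x$train_duration,
    x$train_start, x$amplitude, x$amplitude_units
  ))
  invisible(x)
}

#' Pulse onset times
#'
#' Onsets are `train_start + k / frequency` for `k = 0, 1, ...`; the train
#' interval is half-open, so a pulse whose onset would fall exactly at
#' `train_start + train_duration` is excluded. A 30 s train therefore
#' delivers 15, 30 or 60 pulses at 0.5, 1 or 2 Hz.
#'
#' @param protocol A [stimulus_protocol()].
#' @return Strictly increasing numeric vector of onset times in seconds.
#' @export
pulse_onsets <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n <- floor(protocol$train_duration * protocol$frequency + 1e-9)
  protocol$train_start + seq_len(n) / protocol$frequency - 1 / protocol$frequency
}

#' Stimulation period
#'
#' @param protocol A [stimulus_protocol()].
#' @return `1 / frequency`, in seconds.
#' @export
protocol_period <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  1 / protocol$frequency
}
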