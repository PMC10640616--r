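#' Behaviour-classification thresholds
#'
#' The six entrainment categories are defined verbally (perfect follower,
#' delayed start, early stop, delayed + early, transient freezing, random);
#' these thresholds make them operational. All pulse indices are 0-based.
#'
#' @param response_window Seconds after a pulse onset within which a
#'   contraction is attributed to that pulse; defaults to the stimulation
#'   period when built via [default_behaviour_params()].
#' @param start_delay_pulses A cell is "delayed" (class B component) if its
#'   first matched pulse index exceeds this count.
#' @param early_stop_pulses A cell "stops early" (class C component) if its
#'   last matched pulse is more than this many pulses before the train end.
#' @param freeze_gap_pulses A cell "freezes" (class E) if it misses at
#'   least this many consecutive pulses strictly between its first and last
#'   matched pulses.
#' @param min_matched_fraction Below this matched fraction a cell is
#'   classed as random (F).
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(response_window,
                             start_delay_pulses = 2,
                             early_stop_pulses = 2,
                             freeze_gap_pulses = 2,
                             min_matched_fraction = 0.5) {
  stopifnot(response_window > 0, start_delay_pulses >= 0,
            early_stop_pulses >= 0, freeze_gap_pulses >= 2,
            min_matched_fraction > 0, min_matched_fraction <= 1)
  structure(
    list(response_window = response_window,
         start_delay_pulses = start_delay_pulses,
         early_stop_pulses = early_stop_pulses,
         freeze_gap_pulses = freeze_gap_pulses,
         min_matched_fraction = min_matched_fraction),
    class = "behaviour_params"
  )
}

#' Default behaviour thresholds for a protocol
#'
#' Uses the full stimulation period as the response window (any contraction
#' before the next pulse counts for the current one).
#'
#' @param protocol A [stimulus_protocol()].
#' @inheritParams behaviour_params
#' @return A [behaviour_params()] object.
#' @export
default_behaviour_params <- function(protocol, start_delay_pulses = 2,
                                     early_stop_pulses = 2,
                                     freeze_gap_pulses = 2,
                                     min_matched_fraction = 0.5) {
  behaviour_params(response_window = protocol_period(protocol),
                   start_delay_pulses = start_delay_pulses,
                   early_stop_pulses = early_stop_pulses,
                   freeze_gap_pulses = freeze_gap_pulses,
                   min_matched_fraction = min_matched_fraction)
}

#' Match contraction events to stimulus pulses
#'
#' Greedy chronological matching: for each pulse in order, the earliest
#' still-unassigned contraction with peak time in
#' `[onset, onset + window]` is assigned to it. Contractions outside every
#' window stay unassigned (spontaneous / erratic activity); each event
#' serves at most one pulse.
#'
#' @param events A [contraction_events()] sharing the recording time origin
#'   with the protocol.
#' @param protocol A [stimulus_protocol()].
#' @param window Response window in seconds (default: the stimulation
#'   period).
#' @return A list of class `pulse_response_table`: per-pulse data frame
#'   (`pulse`, `onset_s`, `event_s`, `latency_s`) plus summary fields
#'   `n_pulses`, `n_matched`, `matched_fraction`, `first_matched_index`,
#'   `last_matched_index` (0-based, `NA` when nothing matched),
#'   `max_internal_gap` (longest run of unmatched pulses strictly between
#'   the first and last matched) and `n_unmatched_events`.
#' @export
match_events <- function(events, protocol, window = protocol_period(protocol)) {
  stopifnot(inherits(events, "contraction_events"),
            inherits(protocol, "stimulus_protocol"), window > 0)
  onsets <- pulse_onsets(protocol)
  np <- length(onsets)
  ev <- events$peak_times
  assigned <- rep(FALSE, length(ev))
  event_s <- rep(NA_real_, np)
  for (i in seq_len(np)) {
    ok <- which(!assigned & ev >= onsets[i] & ev <= onsets[i] + window)
    if (length(ok) > 0) {
      j <- ok[1]
      assigned[j] <- TRUE
      event_s[i] <- ev[j]
    }
  }
  matched <- !is.na(event_s)
  idx <- which(matched) - 1L          # 0-based pulse indices
  max_gap <- 0L
  if (length(idx) >= 2) {
    runs <- diff(which(matched)) - 1L
    max_gap <- max(runs)
  }
  structure(
    list(
      table = data.frame(pulse = seq_len(np) - 1L, onset_s = onsets,
                         event_s = event_s, latency_s = event_s - onsets),
      n_pulses = np,
      n_matched = sum(matched),
      matched_fraction = sum(matched) / np,
      first_matched_index = if (any(matched)) idx[1] else NA_integer_,
      last_matched_index = if (any(matched)) idx[length(idx)] else NA_integer_,
      max_internal_gap = max_gap,
      n_unmatched_events = sum(!assigned)
    ),
    class = "pulse_response_table"
  )
}

#' @export
print.pulse_response_table <- function(x, ...) {
  cat(sprintf(
    "<pulse_response_table> %d/%d pulses matched (%.0f%%), first %s, last %s, max gap %d\n",
    x$n_matched, x$n_pulses, 100 * x$matched_fraction,
    x$first_matched_index, x$last_matched_index, x$max_internal_gap
  ))
  invisible(x)
}

#' Classify a cell's entrainment behaviour
#'
#' Assigns one of the six categories from the pulse-response summary, in
#' this order of precedence:
#' \describe{
#'   \item{F}{random / erratic: matched fraction below
#'     `min_matched_fraction`, or no matches at all.}
#'   \item{D}{delayed start and early stop combined.}
#'   \item{B}{delayed start: first matched pulse index greater than
#'     `start_delay_pulses`.}
#'   \item{C}{early stop: last matched pulse more than `early_stop_pulses`
#'     before the end of the train.}
#'   \item{E}{transient freezing: at least `freeze_gap_pulses` consecutive
#'     missed pulses inside an otherwise matched span.}
#'   \item{A}{perfect follower: none of the above.}
#' }
#'
#' @param table A `pulse_response_table` from [match_events()].
#' @param params A [behaviour_params()].
#' @return A single character, one of `"A"` to `"F"`.
#' @export
classify <- function(table, params) {
  stopifnot(inherits(table, "pulse_response_table"),
            inherits(params, "behaviour_params"))
  if (table$n_matched == 0 ||
      table$matched_fraction < params$min_matched_fraction) {
    return("F")
  }
  np <- table$n_pulses
  delayed <- table$first_matched_index > params$start_delay_pulses
  early <- table$last_matched_index < np - 1 - params$early_stop_pulses
  frozen <- table$max_internal_gap >= params$freeze_gap_pulses
  if (delayed && early) "D"
  else if (delayed) "B"
  else if (early) "C"
  else if (frozen) "E"
  else "A"
}

#' Population distribution of behaviour classes
#'
#' Per-class percentages with the count-based error bar sqrt(N), expressed
#' in percent, used for population bar charts.
#'
#' @param classes Character vector of class labels (`"A"`..`"F"`).
#' @return Data frame with columns `class`, `n`, `percent`,
#'   `error_percent` (`sqrt(n)`), covering all six classes.
#' @export
behaviour_distribution <- function(classes) {
  if (length(classes) == 0) stop("empty class list")
  lv <- c("A", "B", "C", "D", "E", "F")
  stopifnot(all(classes %in% lv))
  n <- as.integer(table(factor(classes, levels = lv)))
  data.frame(class = lv, n = n,
             percent = 100 * n / length(classes),
             error_percent = sqrt(n))
}
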