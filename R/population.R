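#' Population summary of contraction frequencies
#'
#' Aggregates per-cell mean contraction frequencies into the statistics
#' reported for a paced cohort: mean, standard deviation, standard error of
#' the mean, the fraction of cells whose frequency lies within
#' `tolerance * target` of the pacing target, and a histogram whose bin
#' width is the sample SEM rounded to one significant figure, with bins
#' anchored at zero.
#'
#' @param frequencies Per-cell frequencies in Hz (all > 0).
#' @param target Pacing target frequency in Hz.
#' @param tolerance At-target window as a fraction of `target` (default
#'   0.10).
#' @return A list of class `population_summary` with fields `n`,
#'   `per_cell_frequencies`, `mean`, `sd`, `sem`, `target_frequency`,
#'   `fraction_at_target`, `bin_width`, `breaks`, `counts`,
#'   `count_error_percent`.
#' @export
summarize_population <- function(frequencies, target, tolerance = 0.10) {
  stopifnot(length(frequencies) >= 1, all(frequencies > 0), target > 0,
            tolerance >= 0)
  n <- length(frequencies)
  m <- mean(frequencies)
  s <- stats::sd(frequencies)
  if (is.na(s)) s <- 0
  sem <- s / sqrt(n)
  at_target <- abs(frequencies - target) <= tolerance * target
  bw <- signif_bin_width(sem, fallback = max(frequencies) / 10)
  breaks <- seq(0, (floor(max(frequencies) / bw) + 1) * bw, by = bw)
  counts <- as.integer(table(cut(frequencies, breaks,
                                 include.lowest = TRUE, right = FALSE)))
  structure(
    list(n = n, per_cell_frequencies = frequencies, mean = m, sd = s,
         sem = sem, target_frequency = target,
         fraction_at_target = mean(at_target), bin_width = bw,
         breaks = breaks, counts = counts,
         count_error_percent = count_error_percent(n)),
    class = "population_summary"
  )
}

# SEM rounded to one significant figure; fall back for degenerate samples
signif_bin_width <- function(sem, fallback) {
  if (!is.finite(sem) || sem <= 0) {
    bw <- signif(fallback, 1)
    if (bw <= 0) bw <- 0.1
    return(bw)
  }
  signif(sem, 1)
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf(
    "<population_summary> n = %d, mean %.3f +/- %.3f (sd) Hz, sem %.3f Hz\n  %.0f%% at target %g Hz, bin width %g Hz, count error sqrt(N) = %.1f%%\n",
    x$n, x$mean, x$sd, x$sem, 100 * x$fraction_at_target,
    x$target_frequency, x$bin_width, x$count_error_percent
  ))
  invisible(x)
}

#' Count-based error bar
#'
#' The error bar attached to a count of N observations is `sqrt(N)`,
#' read as a percentage in bar charts of population fractions.
#'
#' @param n Non-negative count.
#' @return `sqrt(n)` (a percentage).
#' @export
count_error_percent <- function(n) {
  stopifnot(n >= 0)
  sqrt(n)
}

#' Activation dose-response curve
#'
#' Fraction of fields (or cells) showing at least one triggered contraction
#' at each stimulus level. 100% at a level means every trial at that level
#' had a responder.
#'
#' @param trials Data frame with columns `level` (stimulus amplitude) and
#'   `responded` (logical).
#' @param units Unit label for the levels.
#' @return A list of class `activation_curve` with a data frame `curve`
#'   (`level`, `fraction_percent`, `n`) ordered by increasing level.
#' @export
activation_curve <- function(trials, units = "") {
  stopifnot(is.data.frame(trials), all(c("level", "responded") %in%
                                         names(trials)),
            nrow(trials) >= 1)
  lv <- sort(unique(trials$level))
  frac <- vapply(lv, function(l) {
    100 * mean(trials$responded[trials$level == l])
  }, numeric(1))
  nn <- vapply(lv, function(l) sum(trials$level == l), numeric(1))
  structure(
    list(curve = data.frame(level = lv, fraction_percent = frac, n = nn),
         units = units),
    class = "activation_curve"
  )
}

#' Pair optical and electrical doses at equal activation
#'
#' For each target activation percentage, linearly interpolates both
#' dose-response curves to find the stimulus level reaching it, pairing the
#' voltage with the equivalent light power density.
#'
#' @param curve_opt,curve_el [activation_curve()] objects (optical and
#'   electrical).
#' @param targets Activation percentages to pair.
#' @return Data frame `activation_percent`, `level_optical`,
#'   `level_electrical`.
#' @export
pair_equivalent_doses <- function(curve_opt, curve_el, targets) {
  stopifnot(inherits(curve_opt, "activation_curve"),
            inherits(curve_el, "activation_curve"))
  level_at <- function(curve, tgt) {
    cv <- curve$curve
    if (tgt < min(cv$fraction_percent) || tgt > max(cv$fraction_percent)) {
      stop(sprintf("target activation %g%% outside the measured curve", tgt))
    }
    # first level reaching the target along the increasing-dose axis
    i <- which(cv$fraction_percent >= tgt)[1]
    if (cv$fraction_percent[i] == tgt || i == 1) return(cv$level[i])
    f0 <- cv$fraction_percent[i - 1]; f1 <- cv$fraction_percent[i]
    cv$level[i - 1] + (tgt - f0) / (f1 - f0) * (cv$level[i] - cv$level[i - 1])
  }
  data.frame(
    activation_percent = targets,
    level_optical = vapply(targets, function(t) level_at(curve_opt, t),
                           numeric(1)),
    level_electrical = vapply(targets, function(t) level_at(curve_el, t),
                              numeric(1))
  )
}
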