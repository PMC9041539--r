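#' Event-related (de)synchronization time course
#'
#' Computes the classical band-power ERD/ERS time course: each trial is
#' band-pass filtered, amplitude samples are squared into power samples, power
#' is averaged across trials, smoothed with a moving average, and expressed as
#' the percentage change `100 * (A - R) / R` relative to the mean smoothed
#' power `R` over the pre-stimulus baseline window. Negative values are
#' desynchronization (ERD), positive values synchronization (ERS); the scale
#' is bounded below by -100% because power is nonnegative.
#'
#' @param trials A [trial_set()] whose time axis covers the baseline.
#' @param band [band_definition()]; defaults to mu/alpha 8-13 Hz.
#' @param baseline `c(t0, t1)` seconds, must precede the analysis window;
#'   default the 2 s fixation stage `(-2, 0)`.
#' @param smoothing_len Moving-average length in seconds (default 0.25 s:
#'   shorter than ERD dynamics, longer than one alpha cycle).
#' @return An `erd_timecourse` object: `values` (channels x samples, percent),
#'   `time_axis`, `band`, `baseline`, `smoothing_len`, `n_trials`.
#' @export
#' @examples
#' ts <- trial_set(array(rnorm(4 * 1 * 500), c(4, 1, 500)),
#'                 seq(-1, 0.996, by = 1 / 250), "tMI", "left", 250, "C3")
#' tc <- erd_timecourse(ts, baseline = c(-1, -0.5))
erd_timecourse <- function(trials, band = band_definition("alpha", 8, 13),
                           baseline = c(-2, 0), smoothing_len = 0.25) {
  stopifnot(inherits(trials, "trial_set"))
  if (dim(trials$epochs)[1] < 2) abort("need at least 2 trials")
  if (baseline[1] < trials$time_axis[1] - 1e-9 ||
      baseline[2] > max(trials$time_axis) + 1 / trials$fs) {
    abort("baseline window must lie inside the epoch")
  }
  filtered <- bandpass_trials(trials, band)
  power <- apply(filtered$epochs^2, c(2, 3), mean)  # channels x samples
  k <- max(1L, round(smoothing_len * trials$fs))
  smoothed <- t(apply(power, 1, running_mean, k = k))
  base_idx <- which(trials$time_axis >= baseline[1] &
                      trials$time_axis < baseline[2] - 1e-9)
  R <- rowMeans(smoothed[, base_idx, drop = FALSE])
  if (any(R <= 0)) {
    abort("baseline band power is zero on some channel; cannot normalize")
  }
  values <- 100 * (smoothed - R) / R
  structure(list(values = values, time_axis = trials$time_axis,
                 band = band, baseline = baseline,
                 smoothing_len = smoothing_len,
                 n_trials = dim(trials$epochs)[1],
                 channel_labels = trials$channel_labels,
                 condition = trials$condition, hand = trials$hand),
            class = "erd_timecourse")
}

# centred running mean with shrinking windows at the edges
running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + (k - 1L - half))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.erd_timecourse <- function(x, ...) {
  cat(sprintf("<erd_timecourse> %s band (%g-%g Hz), %d trials, %d channels\n",
              x$band$name, x$band$lo, x$band$hi, x$n_trials,
              nrow(x$values)))
  invisible(x)
}

#' @export
tidy.erd_timecourse <- function(x, ...) {
  tibble(
    time = rep(x$time_axis, each = nrow(x$values)),
    channel = rep(x$channel_labels, length(x$time_axis)),
    erd = as.vector(x$values),
    condition = x$condition, hand = x$hand, band = x$band$name
  )
}

#' @export
autoplot.erd_timecourse <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$erd,
                                   colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to MI onset (s)",
                  y = "band power change vs baseline (%)",
                  title = sprintf("%s/%s, %s band", object$condition,
                                  object$hand, object$band$name)) +
    ggplot2::theme_minimal()
}

#' Summarize an ERD time course over an analysis window
#'
#' Time-average of the percentage time course, one value per channel; the
#' default window is the first half of the MI stage (0-5 s).
#'
#' @param tc An [erd_timecourse()].
#' @param window `c(t0, t1)` seconds inside the time course.
#' @return Tibble with columns `channel`, `erd` (percent), plus the
#'   condition/hand/band labels.
#' @export
erd_summary <- function(tc, window = c(0, 5)) {
  stopifnot(inherits(tc, "erd_timecourse"))
  idx <- which(tc$time_axis >= window[1] & tc$time_axis < window[2] - 1e-9)
  if (length(idx) == 0) abort("summary window contains no samples")
  tibble(channel = tc$channel_labels,
         erd = unname(rowMeans(tc$values[, idx, drop = FALSE])),
         condition = tc$condition, hand = tc$hand, band = tc$band$name)
}

#' Paired contralateral-vs-ipsilateral lateralization test
#'
#' Wilcoxon signed-rank test (two-sided) on paired per-subject ERD summaries
#' at the contralateral and ipsilateral motor channels. A significant negative
#' shift of the contralateral values confirms the expected hemispheric
#' lateralization of mu-band desynchronization during hand imagery.
#'
#' @param contralateral,ipsilateral Numeric vectors, one paired value per
#'   subject (>= 5 pairs).
#' @return One-row tibble: `statistic`, `p.value`, `n`, `n_zero`, `method`.
#' @export
lateralization_test <- function(contralateral, ipsilateral) {
  if (length(contralateral) != length(ipsilateral)) {
    abort("paired inputs must have equal length")
  }
  if (length(contralateral) < 5) abort("need at least 5 paired subjects")
  wilcoxon_signed_rank(contralateral, ipsilateral)
}
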