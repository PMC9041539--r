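# All filtering below is windowed-sinc FIR (Hamming window) applied
# zero-phase: the symmetric kernel is run once and its constant group delay
# removed, after reflect-padding one kernel length at each end to suppress
# boundary transients. Hamming design: ~0.02 dB passband ripple, ~53 dB
# stopband attenuation.

# Hamming windowed-sinc order for a given transition width (Hz); even order so
# the kernel has an integer group delay.
fir_order <- function(transition_hz, fs) {
  ord <- ceiling(3.3 * fs / transition_hz)
  ord + ord %% 2
}

# Zero-phase FIR filtering: single pass of a symmetric (linear-phase) kernel
# with group-delay compensation and reflect padding of one kernel length.
filtfilt_reflect <- function(b, x) {
  nb <- length(b)
  n <- length(x)
  delay <- (nb - 1) %/% 2
  left <- x[pmin(n, seq(nb + 1, 2, by = -1))]
  right <- x[pmax(1, seq(n - 1, n - nb, by = -1))]
  padded <- c(left, x, right)
  yf <- signal::fftfilt(b, padded)
  yf[nb + delay + seq_len(n)]
}

band_kernel <- function(band, fs, n_avail) {
  if (band$hi >= fs / 2) {
    abort(sprintf("band upper edge %g Hz is at or above Nyquist (%g Hz)",
                  band$hi, fs / 2))
  }
  transition <- min(2, 0.25 * band$lo)
  ord <- min(fir_order(transition, fs), floor((n_avail - 1) / 3))
  ord <- max(ord - ord %% 2, 4L)
  signal::fir1(ord, c(band$lo, band$hi) / (fs / 2), type = "pass")
}

#' Zero-phase band-pass filter a recording
#'
#' @param rec An [eeg_recording()].
#' @param band A [band_definition()]; `hi` must be below the Nyquist rate.
#' @return A new filtered [eeg_recording()]; the input is not modified.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 500), 2), 250, c("C3", "C4"))
#' filtered <- bandpass(rec, band_definition("alpha", 8, 13))
bandpass <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(band, "band_definition"))
  b <- band_kernel(band, rec$fs, ncol(rec$data))
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- filtfilt_reflect(b, rec$data[ch, ])
  }
  eeg_recording(out, rec$fs, rec$channel_labels, rec$events)
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (cutoff at 80% of the target
#' Nyquist rate) and keeps every `fs/fs_target`-th sample. Event indices are
#' rescaled with rounding toward zero, so an event stays on or just before its
#' original instant.
#'
#' @param rec An [eeg_recording()].
#' @param fs_target Target rate; `rec$fs` must be an integer multiple.
#' @return The decimated [eeg_recording()].
#' @export
downsample <- function(rec, fs_target) {
  stopifnot(inherits(rec, "eeg_recording"))
  ratio <- rec$fs / fs_target
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("`fs_target` must divide the recording's sampling rate")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  cutoff <- 0.8 * (fs_target / 2)
  ord <- min(fir_order(0.1 * fs_target, rec$fs),
             floor((ncol(rec$data) - 1) / 3))
  ord <- max(ord - ord %% 2, 4L)
  b <- signal::fir1(ord, cutoff / (rec$fs / 2), type = "low")
  b <- b / sum(b)  # exact unity DC gain so constants pass through unchanged
  keep <- seq(1L, ncol(rec$data), by = ratio)
  out <- matrix(0, nrow(rec$data), length(keep),
                dimnames = list(rec$channel_labels, NULL))
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- filtfilt_reflect(b, rec$data[ch, ])[keep]
  }
  ev <- rec$events
  if (nrow(ev) > 0) ev$sample <- (ev$sample - 1L) %/% ratio + 1L
  eeg_recording(out, fs_target, rec$channel_labels, ev)
}

#' Epoched trials for one condition and hand
#'
#' @param epochs 3-way array, trials x channels x samples.
#' @param time_axis Seconds relative to MI onset, one value per sample.
#' @param condition,hand Labels.
#' @param fs Sampling rate (Hz).
#' @param channel_labels Channel labels matching dim 2.
#' @param subject_id Optional subject identifier.
#' @return A `trial_set` object.
#' @export
trial_set <- function(epochs, time_axis, condition, hand, fs, channel_labels,
                      subject_id = NA_character_) {
  stopifnot(length(dim(epochs)) == 3,
            dim(epochs)[3] == length(time_axis),
            dim(epochs)[2] == length(channel_labels))
  if (length(time_axis) > 1) {
    dt <- diff(time_axis)
    stopifnot(max(abs(dt - 1 / fs)) < 1e-6)
  }
  dimnames(epochs) <- list(NULL, channel_labels, NULL)
  structure(list(epochs = epochs, time_axis = time_axis,
                 condition = condition, hand = hand, fs = fs,
                 channel_labels = channel_labels, subject_id = subject_id),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %s/%s: %d trials x %d channels x %d samples @ %g Hz [%g, %g) s\n",
              x$condition, x$hand, dim(x$epochs)[1], dim(x$epochs)[2],
              dim(x$epochs)[3], x$fs, x$time_axis[1],
              x$time_axis[length(x$time_axis)] + 1 / x$fs))
  invisible(x)
}

#' Extract per-trial epochs grouped by condition and hand
#'
#' Cuts a window around every event (MI onset = time 0) and groups the
#' resulting epochs by (condition, hand).
#'
#' @param rec An [eeg_recording()] with a populated event table.
#' @param window Numeric `c(t0, t1)` in seconds relative to each event; the
#'   epoch holds `round((t1 - t0) * fs)` samples starting at `t0`.
#' @param subject_id Carried into each [trial_set()].
#' @return Named list of [trial_set()] objects, one per observed
#'   condition x hand combination (names `"condition.hand"`).
#' @export
epoch_trials <- function(rec, window = c(-2, 13), subject_id = NA_character_) {
  stopifnot(inherits(rec, "eeg_recording"), length(window) == 2,
            window[2] > window[1])
  if (nrow(rec$events) == 0) abort("recording has no events to epoch around")
  n_samp <- round((window[2] - window[1]) * rec$fs)
  offset <- round(window[1] * rec$fs)
  n_total <- ncol(rec$data)
  starts <- rec$events$sample + offset
  bad <- which(starts < 1 | starts + n_samp - 1 > n_total)
  if (length(bad) > 0) {
    abort(sprintf(
      "window [%g, %g] s exceeds the recording at event %d (sample %d, %s/%s)",
      window[1], window[2], bad[1], rec$events$sample[bad[1]],
      rec$events$condition[bad[1]], rec$events$hand[bad[1]]))
  }
  time_axis <- window[1] + (seq_len(n_samp) - 1) / rec$fs
  groups <- split(seq_len(nrow(rec$events)),
                  interaction(rec$events$condition, rec$events$hand,
                              drop = TRUE, lex.order = TRUE))
  purrr::map(groups, function(idx) {
    ep <- array(0, dim = c(length(idx), nrow(rec$data), n_samp))
    for (i in seq_along(idx)) {
      s0 <- starts[idx[i]]
      ep[i, , ] <- rec$data[, s0:(s0 + n_samp - 1), drop = FALSE]
    }
    trial_set(ep, time_axis, rec$events$condition[idx[1]],
              rec$events$hand[idx[1]], rec$fs, rec$channel_labels, subject_id)
  })
}

# band-pass every trial x channel series of a trial_set; returns a trial_set
bandpass_trials <- function(trials, band) {
  stopifnot(inherits(trials, "trial_set"))
  b <- band_kernel(band, trials$fs, dim(trials$epochs)[3])
  ep <- trials$epochs
  for (tr in seq_len(dim(ep)[1])) {
    for (ch in seq_len(dim(ep)[2])) {
      ep[tr, ch, ] <- filtfilt_reflect(b, trials$epochs[tr, ch, ])
    }
  }
  trial_set(ep, trials$time_axis, trials$condition, trials$hand, trials$fs,
            trials$channel_labels, trials$subject_id)
}

# crop a trial_set to a time window (seconds relative to MI onset)
crop_trials <- function(trials, window) {
  keep <- which(trials$time_axis >= window[1] &
                  trials$time_axis < window[2] - 1e-9)
  if (length(keep) == 0) abort("crop window contains no samples")
  trial_set(trials$epochs[, , keep, drop = FALSE], trials$time_axis[keep],
            trials$condition, trials$hand, trials$fs, trials$channel_labels,
            trials$subject_id)
}
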