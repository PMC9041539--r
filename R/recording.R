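#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous EEG signal: a channels-by-samples
#' numeric matrix (microvolts), its sampling rate, and an event table marking
#' trial onsets (sample index of imagery onset, task condition, imagined
#' hand).
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per row of `data`.
#' @param events Tibble/data frame with columns `sample` (1-based onset index),
#'   `condition`, `hand`. May have zero rows.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels, events = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric channels x samples matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number")
  }
  if (length(channel_labels) != nrow(data)) {
    abort("`channel_labels` length must equal nrow(data)")
  }
  if (anyDuplicated(channel_labels)) {
    abort("`channel_labels` must be unique")
  }
  if (is.null(events)) {
    events <- tibble(sample = integer(), condition = character(), hand = character())
  }
  events <- as_tibble(events)
  stopifnot(all(c("sample", "condition", "hand") %in% names(events)))
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data)))) {
    abort("event sample indices must lie within the recording")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         events = events),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

#' Frequency band definition
#'
#' @param name Band label (e.g. `"alpha"`).
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `band_definition` list.
#' @export
#' @examples
#' band_definition("alpha", 8, 13)
band_definition <- function(name, lo, hi) {
  if (!(is.numeric(lo) && is.numeric(hi) && lo > 0 && hi > lo)) {
    abort("band edges must satisfy 0 < lo < hi")
  }
  structure(list(name = as.character(name), lo = lo, hi = hi),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' Default analysis bands
#'
#' Alpha (8-13 Hz) and beta (13-30 Hz) are the classification sub-bands;
#' connectivity uses alpha (8-13), beta (14-30) and gamma (31-50 Hz). The two
#' beta conventions are kept distinct on purpose: the classification and
#' connectivity stages of the workflow define beta differently, and the
#' defaults record each stage's own convention.
#'
#' @return A named list of `band_definition` objects.
#' @export
default_bands <- function() {
  list(
    classification = list(
      alpha = band_definition("alpha", 8, 13),
      beta  = band_definition("beta", 13, 30)
    ),
    connectivity = list(
      alpha = band_definition("alpha", 8, 13),
      beta  = band_definition("beta", 14, 30),
      gamma = band_definition("gamma", 31, 50)
    )
  )
}

#' The nine-channel analysis montage
#'
#' Frontal, central and parietal electrodes used for connectivity analysis.
#' @return Character vector of nine channel labels.
#' @export
analysis_montage <- function() {
  c("F3", "Fz", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4")
}
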