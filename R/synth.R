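#' Configuration for a synthetic motor-imagery EEG session
#'
#' Describes one synthetic session of the three-condition, two-hand
#' motor-imagery paradigm. Each trial consists of a fixation stage (-2 to 0 s),
#' a motor-imagery stage (0 to 10 s) and a rest stage (10 to 13 s); every
#' condition is run 20 times per hand, giving 120 trials per session under the
#' defaults. Channels carry 1/f-flavoured background noise; the two motor
#' channels additionally carry a narrowband mu/alpha oscillation whose
#' amplitude is attenuated by `erd_depth` on the channel contralateral to the
#' imagined hand during the MI stage only (the planted event-related
#' desynchronization). Directed couplings inject a delayed, band-limited copy
#' of a source channel into a sink channel during the MI stage of the listed
#' conditions.
#'
#' @param channels Ordered channel labels; must contain the entries of
#'   `erd_channels` and all coupling endpoints.
#' @param fs_native Sampling rate of the generated recording, Hz.
#' @param n_trials_per_hand Trials per condition and hand.
#' @param conditions Condition labels.
#' @param stage_durations Named numeric: `fixation`, `mi`, `rest` durations (s).
#' @param erd_channels Named character: which channel is attenuated for each
#'   hand (contralateral mapping: left hand -> C4, right hand -> C3).
#' @param erd_depth Amplitude attenuation factor in (0, 1]; band power during
#'   MI scales as `erd_depth^2`, so 0.5 plants an ERD of about -75%.
#' @param alpha_freq Centre frequency of the mu/alpha oscillation, Hz.
#' @param alpha_amp Root-mean-square amplitude of the oscillation (same units
#'   as `noise_sd`).
#' @param couplings List of [coupling()] specifications.
#' @param noise_sd Standard deviation of the broadband background noise.
#' @param seed Session seed; per-trial seeds are spawned deterministically
#'   from it.
#'
#' @return A validated `synth_config` object.
#' @export
#' @examples
#' cfg <- synth_config(n_trials_per_hand = 2, fs_native = 250)
#' cfg$n_trials_per_hand
synth_config <- function(channels = analysis_montage(),
                         fs_native = 1000,
                         n_trials_per_hand = 20,
                         conditions = c("tMI", "rmMI", "bcMI"),
                         stage_durations = c(fixation = 2, mi = 10, rest = 3),
                         erd_channels = c(left = "C4", right = "C3"),
                         erd_depth = 0.5,
                         alpha_freq = 10,
                         alpha_amp = 2,
                         couplings = default_couplings(),
                         noise_sd = 1,
                         seed = 1L) {
  cfg <- structure(
    list(channels = as.character(channels), fs_native = fs_native,
         n_trials_per_hand = as.integer(n_trials_per_hand),
         conditions = as.character(conditions),
         stage_durations = stage_durations, erd_channels = erd_channels,
         erd_depth = erd_depth, alpha_freq = alpha_freq,
         alpha_amp = alpha_amp, couplings = couplings,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("invalid synth_config: field `%s` %s", field, msg),
          class = "micnet_config_error")
  }
  if (anyDuplicated(cfg$channels)) bad("channels", "must be unique")
  if (!is.numeric(cfg$fs_native) || cfg$fs_native <= 0) {
    bad("fs_native", "must be a positive sampling rate")
  }
  if (cfg$n_trials_per_hand < 1) bad("n_trials_per_hand", "must be >= 1")
  sd_names <- c("fixation", "mi", "rest")
  if (!all(sd_names %in% names(cfg$stage_durations)) ||
      any(cfg$stage_durations[sd_names] <= 0)) {
    bad("stage_durations", "must name positive fixation/mi/rest durations")
  }
  if (!(cfg$erd_depth > 0 && cfg$erd_depth <= 1)) {
    bad("erd_depth", "must lie in (0, 1]")
  }
  if (!all(cfg$erd_channels %in% cfg$channels)) {
    bad("erd_channels", "must reference channels present in `channels`")
  }
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be positive")
  if (cfg$alpha_amp < 0) bad("alpha_amp", "must be nonnegative")
  for (cp in cfg$couplings) {
    if (!inherits(cp, "micnet_coupling")) bad("couplings", "must be coupling() objects")
    if (cp$lag < 1) bad("couplings", "must have lag >= 1 sample")
    if (!all(c(cp$source, cp$sink) %in% cfg$channels)) {
      bad("couplings", sprintf("references unknown channel in %s->%s",
                               cp$source, cp$sink))
    }
    if (!all(cp$conditions %in% cfg$conditions)) {
      bad("couplings", "references an unknown condition")
    }
  }
  cfg
}

#' Planted directed coupling
#'
#' @param source,sink Channel labels.
#' @param conditions Conditions in which the coupling is active.
#' @param lag Delay in samples (at the native rate), >= 1.
#' @param strength Scaling applied to the delayed band-limited source.
#' @param band A [band_definition()]; the source is filtered to this band
#'   before injection so band-resolved contrasts can recover it.
#' @return A `micnet_coupling` object.
#' @export
coupling <- function(source, sink, conditions, lag, strength,
                     band = band_definition("beta", 14, 30)) {
  structure(list(source = source, sink = sink,
                 conditions = as.character(conditions),
                 lag = as.integer(lag), strength = strength, band = band),
            class = "micnet_coupling")
}

#' Default planted couplings: parieto-central and parieto-frontal edges active
#' only in the bimanual-coordination condition, mimicking the kind of
#' condition-specific information flow the contrast stage is meant to detect.
#' @return List of [coupling()] objects.
#' @export
default_couplings <- function() {
  list(
    coupling("Pz", "Cz", "bcMI", lag = 8, strength = 0.8,
             band = band_definition("beta", 14, 30)),
    coupling("P3", "F4", "bcMI", lag = 8, strength = 0.8,
             band = band_definition("beta", 14, 30))
  )
}

# deterministic per-trial seed spawned from the session seed (counter scheme)
spawn_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 16807) %% 2147483647)
}

# 1/f-flavoured noise: white Gaussian plus a weak pink component shaped in the
# frequency domain (amplitude ~ f^{-1/2}), avoiding artifact modelling.
pink_noise <- function(n, sd = 1) {
  w <- rnorm(n)
  f <- seq_len(n) - 1
  fbin <- pmax(1, pmin(f, n - f))  # symmetric frequency index, DC clamped
  shape <- 1 / sqrt(fbin)
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
  x * sd / stats::sd(x)
}

# narrowband oscillation realised as band-filtered white noise, unit RMS
narrowband_noise <- function(n, fs, lo, hi) {
  ord <- min(fir_order(2, fs), floor((n - 1) / 3))
  ord <- ord + ord %% 2
  b <- signal::fir1(ord, c(lo, hi) / (fs / 2), type = "pass")
  x <- filtfilt_reflect(b, rnorm(n))
  x / stats::sd(x)
}

#' Generate one synthetic motor-imagery session
#'
#' Produces a continuous recording in which trials are laid out back to back,
#' each spanning fixation + MI + rest; the event table marks the MI onset of
#' every trial. Trial order is randomised from the session seed; each trial's
#' noise is drawn from its own spawned seed so single trials are reproducible
#' independently of the rest of the session.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording` (an [eeg_recording()] whose
#'   `events` table holds one row per trial) and `ground_truth` (list with a
#'   per-trial tibble `trials` and the planted `edges` tibble).
#' @export
#' @examples
#' sess <- generate_session(synth_config(
#'   channels = c("C3", "C4"), fs_native = 100, n_trials_per_hand = 1,
#'   conditions = "tMI", couplings = list()))
#' nrow(sess$recording$events)
generate_session <- function(config) {
  config <- validate_synth_config(config)
  fs <- config$fs_native
  durs <- config$stage_durations
  n_fix <- round(durs[["fixation"]] * fs)
  n_mi <- round(durs[["mi"]] * fs)
  n_rest <- round(durs[["rest"]] * fs)
  n_trial <- n_fix + n_mi + n_rest
  hands <- names(config$erd_channels)

  plan <- expand.grid(rep = seq_len(config$n_trials_per_hand),
                      hand = hands, condition = config$conditions,
                      stringsAsFactors = FALSE)
  set.seed(config$seed)
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
  n_trials <- nrow(plan)

  nch <- length(config$channels)
  data <- matrix(0, nch, n_trials * n_trial,
                 dimnames = list(config$channels, NULL))
  mi_idx <- n_fix + seq_len(n_mi)
  motor_channels <- unique(unname(config$erd_channels))

  for (tr in seq_len(n_trials)) {
    set.seed(spawn_seed(config$seed, tr))
    seg <- matrix(0, nch, n_trial)
    for (ch in seq_len(nch)) {
      seg[ch, ] <- config$noise_sd *
        (rnorm(n_trial) + 0.5 * pink_noise(n_trial)) / sqrt(1.25)
    }
    # mu/alpha rhythm on the motor channels, suppressed contralaterally
    half_bw <- 2.5
    erd_ch <- config$erd_channels[[plan$hand[tr]]]
    for (ch_lab in motor_channels) {
      osc <- config$alpha_amp * narrowband_noise(
        n_trial, fs, config$alpha_freq - half_bw, config$alpha_freq + half_bw)
      gain <- rep(1, n_trial)
      if (ch_lab == erd_ch) gain[mi_idx] <- config$erd_depth
      seg[match(ch_lab, config$channels), ] <-
        seg[match(ch_lab, config$channels), ] + gain * osc
    }
    # directed couplings active in this trial's condition, MI stage only
    for (cp in config$couplings) {
      if (!(plan$condition[tr] %in% cp$conditions)) next
      src <- seg[match(cp$source, config$channels), ]
      ord <- min(fir_order(2, fs), floor((n_trial - 1) / 3))
      ord <- ord + ord %% 2
      b <- signal::fir1(ord, c(cp$band$lo, cp$band$hi) / (fs / 2), type = "pass")
      src_b <- filtfilt_reflect(b, src)
      lagged <- c(rep(0, cp$lag), src_b[seq_len(n_trial - cp$lag)])
      sink_row <- match(cp$sink, config$channels)
      seg[sink_row, mi_idx] <- seg[sink_row, mi_idx] +
        cp$strength * lagged[mi_idx]
    }
    data[, (tr - 1L) * n_trial + seq_len(n_trial)] <- seg
  }

  events <- tibble(
    sample = (seq_len(n_trials) - 1L) * n_trial + n_fix + 1L,
    condition = plan$condition, hand = plan$hand
  )
  rec <- eeg_recording(data, fs, config$channels, events)
  gt <- list(
    trials = tibble(trial = seq_len(n_trials), condition = plan$condition,
                    hand = plan$hand, onset_sample = events$sample,
                    erd_channel = unname(config$erd_channels[plan$hand]),
                    erd_depth = config$erd_depth),
    edges = edges_tibble(config$couplings)
  )
  list(recording = rec, ground_truth = gt)
}

edges_tibble <- function(couplings) {
  if (length(couplings) == 0) {
    return(tibble(source = character(), sink = character(),
                  conditions = character(), lag = integer(),
                  strength = numeric(), band = character()))
  }
  purrr::map_dfr(couplings, function(cp) {
    tibble(source = cp$source, sink = cp$sink,
           conditions = paste(cp$conditions, collapse = ","),
           lag = cp$lag, strength = cp$strength, band = cp$band$name)
  })
}

#' Coupled autoregressive pair with known transfer entropy
#'
#' Generates `X` as unit-variance white Gaussian noise and
#' `Y[t] = c * X[t - lag] + e[t]` with Gaussian innovations of standard
#' deviation `sd_noise`. For this linear-Gaussian system the population
#' transfer entropy is available in closed form,
#' `TE(X -> Y) = 0.5 * log(1 + c^2 / sd_noise^2)` nats and `TE(Y -> X) = 0`,
#' which makes the pair the canonical oracle for the k-NN estimator.
#'
#' @param n Series length, >= 100.
#' @param c_strength Coupling coefficient.
#' @param lag Coupling delay in samples, >= 1.
#' @param sd_noise Innovation standard deviation, > 0.
#' @param seed Integer seed.
#' @return List with series `x`, `y`, the generating parameters, and
#'   `te_population` (nats).
#' @export
#' @examples
#' p <- generate_coupled_ar(500, c_strength = 1, seed = 7)
#' p$te_population  # 0.5 * log(2)
generate_coupled_ar <- function(n, c_strength = 1, lag = 1, sd_noise = 1,
                                seed = 1L) {
  if (n < 100) abort("`n` must be >= 100")
  if (lag < 1) abort("`lag` must be >= 1")
  if (sd_noise <= 0) abort("`sd_noise` must be positive")
  set.seed(seed)
  x <- rnorm(n)
  eps <- rnorm(n, sd = sd_noise)
  y <- eps
  idx <- (lag + 1):n
  y[idx] <- c_strength * x[idx - lag] + eps[idx]
  list(x = x, y = y, c_strength = c_strength, lag = lag, sd_noise = sd_noise,
       seed = seed,
       te_population = 0.5 * log(1 + c_strength^2 / sd_noise^2))
}
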