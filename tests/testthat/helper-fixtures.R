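# shared fixtures, generated once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# miniature session: 3 conditions x 2 hands x 4 trials, 2 s MI stage, 250 Hz
tiny_config <- function(n_trials_per_hand = 4, seed = 101L, ...) {
  synth_config(fs_native = 250, n_trials_per_hand = n_trials_per_hand,
               stage_durations = c(fixation = 2, mi = 2, rest = 1),
               seed = seed, ...)
}

tiny_session <- function() cached("tiny_session", generate_session(tiny_config()))

tiny_trials <- function() {
  cached("tiny_trials", epoch_trials(tiny_session()$recording, c(-2, 3)))
}

# two-channel session for ERD checks: 50 trials per hand, one condition
erd_config <- function(erd_depth = 0.5, seed = 11L, n_per_hand = 50L) {
  synth_config(channels = c("C3", "C4"), fs_native = 250,
               n_trials_per_hand = n_per_hand, conditions = "tMI",
               couplings = list(), erd_depth = erd_depth, seed = seed)
}

erd_trials <- function() {
  cached("erd_trials", {
    sess <- generate_session(erd_config())
    epoch_trials(sess$recording, c(-2, 13))
  })
}

# strongly separable left/right data for classification checks
sep_trials <- function() {
  cached("sep_trials", {
    cfg <- synth_config(channels = c("F3", "C3", "Cz", "C4", "P3"),
                        fs_native = 250, n_trials_per_hand = 20,
                        conditions = "tMI", couplings = list(),
                        erd_depth = 0.2, noise_sd = 0.5, seed = 4L,
                        stage_durations = c(fixation = 2, mi = 4, rest = 1))
    tr <- epoch_trials(generate_session(cfg)$recording, c(-2, 5))
    list(left = crop_trials_public(tr[["tMI.left"]], c(0, 4)),
         right = crop_trials_public(tr[["tMI.right"]], c(0, 4)))
  })
}

crop_trials_public <- function(trials, window) {
  keep <- which(trials$time_axis >= window[1] &
                  trials$time_axis < window[2] - 1e-9)
  trial_set(trials$epochs[, , keep, drop = FALSE], trials$time_axis[keep],
            trials$condition, trials$hand, trials$fs, trials$channel_labels,
            trials$subject_id)
}

# brute-force two-sided signed-rank p by enumerating all 2^n sign patterns
enum_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- drop(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# brute-force Benjamini-Hochberg step-up from its definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(adj))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# sinusoid helper
sine_recording <- function(freq, fs = 250, dur = 8, channels = "C3") {
  t <- seq(0, dur, by = 1 / fs)
  eeg_recording(matrix(rep(sin(2 * pi * freq * t), length(channels)),
                       nrow = length(channels), byrow = TRUE),
                fs, channels)
}
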