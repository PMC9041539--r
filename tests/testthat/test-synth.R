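test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synth_config(erd_depth = 0), "erd_depth",
               class = "micnet_config_error")
  expect_error(synth_config(erd_depth = 1.2), "erd_depth")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(erd_channels = c(left = "XX", right = "C3")),
               "erd_channels")
  expect_error(
    synth_config(couplings = list(coupling("Pz", "Cz", "bcMI", lag = 0,
                                           strength = 1))),
    "lag")
  expect_error(
    synth_config(couplings = list(coupling("Pz", "QQ", "bcMI", lag = 2,
                                           strength = 1))),
    "couplings")
})

test_that("session layout matches the paradigm: trials, events, stages", {
  sess <- tiny_session()
  cfg <- tiny_config()
  n_expected <- length(cfg$conditions) * 2 * cfg$n_trials_per_hand
  expect_equal(nrow(sess$recording$events), n_expected)
  expect_equal(nrow(sess$ground_truth$trials), n_expected)
  # every condition x hand cell holds exactly n_trials_per_hand trials
  tab <- table(sess$recording$events$condition, sess$recording$events$hand)
  expect_true(all(tab == cfg$n_trials_per_hand))
  # trial slots are contiguous: recording length = trials x (fix + mi + rest)
  slot <- sum(cfg$stage_durations) * cfg$fs_native
  expect_equal(ncol(sess$recording$data), n_expected * slot)
  # MI onset sits one fixation length into each slot
  expect_equal(sess$recording$events$sample[1],
               cfg$stage_durations[["fixation"]] * cfg$fs_native + 1)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- tiny_config(n_trials_per_hand = 2)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$recording$events, s2$recording$events)
  s3 <- generate_session(tiny_config(n_trials_per_hand = 2, seed = 999L))
  expect_false(identical(s1$recording$data, s3$recording$data))
})

test_that("with no planted ERD, MI-stage alpha power matches fixation power", {
  cfg <- erd_config(erd_depth = 1, seed = 21L, n_per_hand = 100L)
  sess <- generate_session(cfg)
  trials <- epoch_trials(sess$recording, c(-2, 13))
  # no attenuation planted: the expected percentage power change is zero.
  # A single channel's 2 s baseline carries few independent band-power
  # samples, so the Monte-Carlo estimate pools both motor channels and both
  # hands (4 x 100 trials) before applying the 5-point equivalence band.
  vals <- unlist(lapply(trials, function(ts) {
    erd_summary(erd_timecourse(ts), window = c(0, 5))$erd
  }))
  expect_lt(abs(mean(vals)), 5)
  expect_lt(max(abs(vals)), 15)  # and no single cell drifts far from zero
})

test_that("the coupled AR pair has the advertised structure", {
  p <- generate_coupled_ar(20000, c_strength = 1, lag = 3, sd_noise = 1,
                           seed = 8)
  expect_equal(p$te_population, 0.5 * log(2))
  # regression of y on lagged x recovers the coupling coefficient
  idx <- 4:20000
  fit <- stats::lm.fit(cbind(1, p$x[idx - 3]), p$y[idx])
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 0.05)
  # uncoupled: cross-correlation at the lag vanishes
  q <- generate_coupled_ar(20000, c_strength = 0, lag = 3, seed = 9)
  cc <- stats::cor(q$x[1:19997], q$y[4:20000])
  expect_lt(abs(cc), 0.03)
  expect_error(generate_coupled_ar(50), "n")
  expect_error(generate_coupled_ar(500, sd_noise = 0), "sd_noise")
  expect_error(generate_coupled_ar(500, lag = 0), "lag")
})

test_that("planted couplings are recoverable as a TE direction preference", {
  # strength >= 0.5: the planted source -> sink direction dominates in most
  # seeds (tiny sessions, beta band, fixed embedding)
  beta <- band_definition("beta", 14, 30)
  hits <- vapply(1:8, function(s) {
    cfg <- synth_config(fs_native = 250, n_trials_per_hand = 6,
                        stage_durations = c(fixation = 2, mi = 3, rest = 0.5),
                        conditions = "bcMI", seed = 300L + s)
    tr <- epoch_trials(generate_session(cfg)$recording, c(-2, 3.5))
    tm <- te_matrix(tr[["bcMI.left"]], beta, window = c(0, 3),
                    params = embedding_params(d = 1, tau = 3),
                    max_points = 900)
    tm$values["Pz", "Cz"] > tm$values["Cz", "Pz"]
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})
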