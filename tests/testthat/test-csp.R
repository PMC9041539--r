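toy_classes <- function(n_trials = 10, n_samp = 200, seed = 42) {
  # class 1 varies only along channel 1, class 2 only along channel 2
  set.seed(seed)
  mk <- function(active) {
    ep <- array(0, c(n_trials, 2, n_samp))
    for (tr in seq_len(n_trials)) {
      ep[tr, active, ] <- rnorm(n_samp)
      ep[tr, 3 - active, ] <- 0.05 * rnorm(n_samp)
    }
    trial_set(ep, seq_len(n_samp) / 100, if (active == 1) "a" else "b",
              if (active == 1) "left" else "right", 100, c("C3", "C4"))
  }
  list(c1 = mk(1), c2 = mk(2))
}

random_classes <- function(nch = 6, n_trials = 12, n_samp = 150, seed = 7) {
  set.seed(seed)
  mk <- function(cond) {
    A <- matrix(rnorm(nch * nch), nch)
    ep <- array(0, c(n_trials, nch, n_samp))
    for (tr in seq_len(n_trials)) ep[tr, , ] <- A %*% matrix(rnorm(nch * n_samp), nch)
    trial_set(ep, seq_len(n_samp) / 100, cond, "left", 100,
              paste0("ch", seq_len(nch)))
  }
  list(c1 = mk("a"), c2 = mk("b"))
}

test_that("CSP solves the two-class generalized eigenproblem", {
  toy <- toy_classes()
  model <- fit_csp(toy$c1, toy$c2)
  # top filter aligns with the class-1 axis (channel 1)
  w <- model$filters[, 1]
  expect_gt(abs(w[1]) / sqrt(sum(w^2)), 0.99)
  # independent oracle: generalized eigenvalues from solve(R2) %*% R1
  R1 <- micnet:::class_covariance(toy$c1$epochs)
  R2 <- micnet:::class_covariance(toy$c2$epochs)
  ev_oracle <- sort(Re(eigen(solve(R2) %*% R1)$values), decreasing = TRUE)
  expect_equal(model$eigenvalues, ev_oracle, tolerance = 1e-8)
  # identical classes -> all eigenvalues equal
  same <- fit_csp(toy$c1, toy$c1)
  expect_equal(max(same$eigenvalues) / min(same$eigenvalues), 1,
               tolerance = 1e-6)
})

test_that("whitening invariant and eigenvalue duality hold on random data", {
  rc <- random_classes()
  model <- fit_csp(rc$c1, rc$c2)
  R2 <- micnet:::class_covariance(rc$c2$epochs)
  I_hat <- t(model$filters) %*% R2 %*% model$filters
  expect_lt(max(abs(I_hat - diag(nrow(I_hat)))), 1e-6)
  expect_equal(model$eigenvalues, sort(model$eigenvalues, decreasing = TRUE))
  # swapping the classes inverts and reverses the spectrum
  swapped <- fit_csp(rc$c2, rc$c1)
  expect_equal(swapped$eigenvalues, rev(1 / model$eigenvalues),
               tolerance = 1e-8)
})

test_that("CSP features are normalized log-variance shares", {
  toy <- toy_classes()
  model <- fit_csp(toy$c1, toy$c2)
  f1 <- csp_features(model, toy$c1, m = 1)
  expect_equal(ncol(micnet:::feature_cols(f1)), 2)
  # duplicated trial gives identical features
  dup <- trial_set(toy$c1$epochs[c(1, 1), , , drop = FALSE],
                   toy$c1$time_axis, "a", "left", 100, c("C3", "C4"))
  fd <- micnet:::feature_cols(csp_features(model, dup, m = 1))
  expect_equal(fd[1, ], fd[2, ])
  # the toy separates: between-class gap dwarfs within-class spread
  f2 <- csp_features(model, toy$c2, m = 1)
  v1 <- micnet:::feature_cols(f1)[, 1]
  v2 <- micnet:::feature_cols(f2)[, 1]
  gap <- abs(mean(v1) - mean(v2))
  expect_gt(gap, 10 * max(sd(v1), sd(v2)))
  expect_error(csp_features(model, toy$c1, m = 3), "m")
  # equal-variance projections give flat features log(1/(2m))
  iso <- trial_set(array(rnorm(2 * 2 * 5000), c(2, 2, 5000)),
                   seq_len(5000) / 100, "a", "left", 100, c("C3", "C4"))
  id_model <- model
  id_model$filters <- diag(2)
  fi <- micnet:::feature_cols(csp_features(id_model, iso, m = 1))
  expect_equal(as.vector(fi), rep(log(0.5), 4), tolerance = 0.05)
})

test_that("Fisher LDA separates and thresholds at the projected midpoint", {
  set.seed(3)
  X <- rbind(matrix(rnorm(100, mean = 3), 50), matrix(rnorm(100, mean = -3), 50))
  lab <- rep(c("l", "r"), each = 50)
  model <- fit_lda(X, lab)
  expect_equal(mean(predict(model, X) == lab), 1)
  # one-dimensional, equal variance: boundary at the midpoint of the means
  x1 <- matrix(c(rnorm(200, 0, 1), rnorm(200, 4, 1)), ncol = 1)
  l1 <- rep(c("a", "b"), each = 200)
  m1 <- fit_lda(x1, l1)
  expect_equal(m1$threshold / m1$w, (mean(x1[1:200]) + mean(x1[201:400])) / 2,
               tolerance = 1e-9)
  # agreement with the MASS reference implementation on fresh data
  skip_if_not_installed("MASS")
  Xt <- matrix(rnorm(200), 100)
  ref <- MASS::lda(X, grouping = lab)
  expect_equal(unname(predict(model, Xt)),
               as.character(predict(ref, Xt)$class))
  # singular scatter advises shrinkage
  Xs <- cbind(rnorm(20), 0)
  expect_error(fit_lda(Xs, rep(c("a", "b"), 10)), "shrinkage")
  expect_s3_class(fit_lda(Xs, rep(c("a", "b"), 10), shrinkage = 0.1),
                  "lda_fisher")
})

test_that("cross-validation is deterministic, stratified and leak-free", {
  sep <- sep_trials()
  cv1 <- cross_validate(sep$left, sep$right, m = 1, repeats = 3, seed = 5)
  cv2 <- cross_validate(sep$left, sep$right, m = 1, repeats = 3, seed = 5)
  expect_identical(cv1$accuracy, cv2$accuracy)
  # near-noiseless planted ERD data separate almost perfectly
  expect_gt(mean(cv1$accuracy), 0.95)
  expect_error(cross_validate(sep$left, sep$right, k = 50), "k")
  # CSP fitted on training trials is unaffected by the held-out trials
  f_a <- fit_csp(crop_trials_public(sep$left, c(0, 2)),
                 crop_trials_public(sep$right, c(0, 2)))
  corrupted <- sep$left
  corrupted$epochs[1, , ] <- 1e3 * corrupted$epochs[1, , ]
  sub <- function(ts) trial_set(ts$epochs[2:20, , ], ts$time_axis,
                                ts$condition, ts$hand, ts$fs,
                                ts$channel_labels)
  expect_identical(fit_csp(sub(sep$left), sub(sep$right))$filters,
                   fit_csp(sub(corrupted), sub(sep$right))$filters)
})

test_that("accuracy is invariant to a consistent channel permutation", {
  sep <- sep_trials()
  perm <- c(3, 1, 5, 2, 4)
  permute <- function(ts) {
    trial_set(ts$epochs[, perm, , drop = FALSE], ts$time_axis, ts$condition,
              ts$hand, ts$fs, ts$channel_labels[perm])
  }
  cv1 <- cross_validate(sep$left, sep$right, m = 1, repeats = 2, seed = 11)
  cv2 <- cross_validate(permute(sep$left), permute(sep$right), m = 1,
                        repeats = 2, seed = 11)
  expect_equal(cv1$accuracy, cv2$accuracy, tolerance = 1e-9)
})

test_that("the m sweep covers the range and breaks ties toward smaller m", {
  sep <- sep_trials()
  sw <- select_m(sep$left, sep$right, m_range = 1:2, repeats = 2, seed = 3)
  expect_equal(sw$sweep$m, 1:2)
  # the toy-like planted data saturate at 100% for both m; the tie rule
  # must pick the smaller m
  if (sw$sweep$mean_accuracy[1] == sw$sweep$mean_accuracy[2]) {
    expect_equal(sw$best_m, 1L)
  } else {
    expect_equal(sw$best_m, sw$sweep$m[which.max(sw$sweep$mean_accuracy)])
  }
})
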