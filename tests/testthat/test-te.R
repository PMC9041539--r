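test_that("delay selection follows autocorrelation decay", {
  set.seed(1)
  expect_equal(select_delay(rnorm(2000)), 1L)
  # sinusoid: acf is a cosine, first < 1/e near a quarter period (6 at 250 Hz)
  s <- sin(2 * pi * 10 * seq(0, 8, by = 1 / 250))
  expect_lte(abs(select_delay(s) - 6L), 1L)
  # AR(1), phi = 0.9: acf = phi^lag, crosses 1/e at ceil(-1/log(0.9)) = 10
  ar <- as.vector(stats::arima.sim(list(ar = 0.9), 4000))
  expect_lte(abs(select_delay(ar) - 10L), 2L)
  expect_error(select_delay(rep(1, 500)), "constant")
  expect_error(select_delay(rnorm(50)), "100")
})

test_that("dimension selection separates stochastic from deterministic series", {
  set.seed(2)
  expect_equal(as.integer(select_dimension(rnorm(1200), tau = 1L)), 1L)
  s <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 250))
  expect_equal(as.integer(select_dimension(s, tau = 6L, d_max = 6L)), 2L)
  ar <- as.vector(stats::arima.sim(list(ar = 0.9), 3000))
  expect_lte(as.integer(select_dimension(ar, tau = 2L, d_max = 5L)), 2L)
  expect_error(select_dimension(rnorm(100), tau = 5L), "short")
})

test_that("TE vanishes for independent series and detects directed coupling", {
  p11 <- embedding_params(d = 1, tau = 1)
  nulls <- vapply(1:6, function(s) {
    set.seed(s)
    te_knn(rnorm(3000), rnorm(3000), p11)
  }, numeric(1))
  expect_lt(mean(abs(nulls)), 0.02)
  # linear-Gaussian oracle: TE(X->Y) = 0.5 ln 2, TE(Y->X) = 0
  p <- generate_coupled_ar(5000, c_strength = 1, sd_noise = 1, seed = 13)
  te_xy <- te_knn(p$y, p$x, p11, max_points = 5000)
  te_yx <- te_knn(p$x, p$y, p11, max_points = 5000)
  expect_equal(te_xy, 0.5 * log(2), tolerance = 0.2)
  expect_lt(abs(te_yx), 0.05)
  expect_gt(te_xy, te_yx)
  expect_error(te_knn(rnorm(20), rnorm(20), p11), "points")
})

test_that("estimator consistency: error shrinks as the series grows", {
  p11 <- embedding_params(d = 1, tau = 1)
  target <- 0.5 * log(2)
  med_err <- vapply(c(500, 2000, 8000), function(n) {
    errs <- vapply(1:5, function(s) {
      p <- generate_coupled_ar(n, c_strength = 1, seed = 100 + s)
      abs(te_knn(p$y, p$x, p11, max_points = n) - target)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) < 0))
})

test_that("Theiler window and affine rescaling leave estimates stable", {
  set.seed(5)
  x <- rnorm(2000); y <- rnorm(2000)
  t0 <- te_knn(x, y, embedding_params(d = 1, tau = 1, theiler = 0))
  t1 <- te_knn(x, y, embedding_params(d = 1, tau = 1, theiler = 1))
  expect_lt(abs(t0 - t1), 0.02)  # within estimator noise on independent data
  # affine invariance via per-dimension standardization
  p <- generate_coupled_ar(2000, c_strength = 1, seed = 6)
  a <- te_knn(p$y, p$x, embedding_params(d = 2, tau = 1))
  b <- te_knn(100 * p$y - 3, -0.02 * p$x + 7, embedding_params(d = 2, tau = 1))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("trial-ensemble pooling accepts trial matrices", {
  # the same coupled pair split into trials estimates the same quantity
  p <- generate_coupled_ar(4000, c_strength = 1, seed = 21)
  whole <- te_knn(p$y, p$x, embedding_params(d = 1, tau = 1), max_points = 4000)
  xm <- matrix(p$x, nrow = 8, byrow = TRUE)
  ym <- matrix(p$y, nrow = 8, byrow = TRUE)
  split <- te_knn(ym, xm, embedding_params(d = 1, tau = 1), max_points = 4000)
  expect_equal(whole, split, tolerance = 0.08)
})

test_that("the TE matrix enumerates all directed pairs over the montage", {
  trials <- tiny_trials()[["bcMI.left"]]
  beta <- band_definition("beta", 14, 30)
  tm <- te_matrix(trials, beta, window = c(0, 2),
                  params = embedding_params(d = 1, tau = 3), max_points = 600)
  expect_equal(dim(tm$values), c(9, 9))
  expect_equal(sum(!is.na(tm$values)), 72)
  expect_true(all(is.na(diag(tm$values))))
  expect_true(all(is.finite(tm$values[upper.tri(tm$values)])))
  expect_equal(nrow(tidy(tm)), 72)
  expect_error(te_matrix(trials, beta, channels = c("F3", "XX")), "XX")
})

test_that("the TE matrix is equivariant under channel permutation", {
  trials <- tiny_trials()[["bcMI.left"]]
  beta <- band_definition("beta", 14, 30)
  sub_ch <- c("F3", "Cz", "Pz")
  perm <- c(2, 3, 1)
  permuted <- trial_set(trials$epochs[, match(sub_ch, trials$channel_labels)[perm], , drop = FALSE],
                        trials$time_axis, trials$condition, trials$hand,
                        trials$fs, sub_ch[perm])
  base <- trial_set(trials$epochs[, match(sub_ch, trials$channel_labels), , drop = FALSE],
                    trials$time_axis, trials$condition, trials$hand,
                    trials$fs, sub_ch)
  prm <- embedding_params(d = 1, tau = 3)
  t_base <- te_matrix(base, beta, window = c(0, 2), channels = sub_ch,
                      params = prm, max_points = 500)
  t_perm <- te_matrix(permuted, beta, window = c(0, 2), channels = sub_ch,
                      params = prm, max_points = 500)
  expect_equal(t_base$values, t_perm$values, tolerance = 1e-9)
})

test_that("relative TE subtracts the baseline elementwise", {
  trials <- tiny_trials()[["bcMI.left"]]
  alpha <- band_definition("alpha", 8, 13)
  prm <- embedding_params(d = 1, tau = 5)
  task <- te_matrix(trials, alpha, window = c(0, 2), params = prm,
                    max_points = 400)
  base <- te_matrix(trials, alpha, window = "baseline", params = prm,
                    max_points = 400)
  rel <- relative_te(task, base)
  expect_equal(rel$values, task$values - base$values)
  expect_equal(rel$window, "relative")
  # task == baseline -> all zeros
  zero <- relative_te(task, task)
  expect_equal(max(abs(zero$values), na.rm = TRUE), 0)
  # linearity under a constant shift
  shifted <- task
  shifted$values <- task$values + 0.3
  expect_equal(relative_te(shifted, base)$values, rel$values + 0.3)
  # montage mismatch errors
  other <- task
  rownames(other$values) <- colnames(other$values) <-
    paste0("X", 1:9)
  expect_error(relative_te(task, other), "montage")
})
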