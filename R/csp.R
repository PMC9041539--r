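#' Fit common spatial patterns for a two-class problem
#'
#' CSP finds spatial filters w maximizing the variance ratio
#' `||w S1||^2 / ||w S2||^2` between the two classes. Per-trial channel
#' covariances `S S^T / t` are trace-normalized (robustness to amplitude
#' drift) and averaged into class covariances R1 and R2; the generalized
#' eigenproblem `R1 w = lambda R2 w` is solved by whitening with R2, so the
#' returned filter matrix E satisfies `E^T R1 E = D` (descending eigenvalues)
#' and `E^T R2 E = I`. The first filters maximize class-1 variance relative to
#' class 2, the last ones the converse.
#'
#' @param class1,class2 [trial_set()] objects with identical channels; the
#'   data are used as given (band-filter and crop to the MI window first).
#' @param band Optional [band_definition()] recorded on the model.
#' @param ridge Ridge regularization added to both class covariances as
#'   `ridge * mean(diag) * I` (default 0; raise it for rank-deficient data).
#' @return A `csp_model`: `filters` (channels x channels, columns ordered by
#'   descending eigenvalue), `eigenvalues`, `band`, `class_labels`.
#' @export
fit_csp <- function(class1, class2, band = NULL, ridge = 0) {
  stopifnot(inherits(class1, "trial_set"), inherits(class2, "trial_set"))
  if (!identical(class1$channel_labels, class2$channel_labels)) {
    abort("the two classes must share the same channels")
  }
  if (dim(class1$epochs)[1] < 2 || dim(class2$epochs)[1] < 2) {
    abort("need at least 2 trials per class")
  }
  R1 <- class_covariance(class1$epochs)
  R2 <- class_covariance(class2$epochs)
  if (ridge > 0) {
    R1 <- R1 + ridge * mean(diag(R1)) * diag(nrow(R1))
    R2 <- R2 + ridge * mean(diag(R2)) * diag(nrow(R2))
  }
  e2 <- eigen(R2, symmetric = TRUE)
  if (min(e2$values) < 1e-10 * max(e2$values)) {
    abort(paste("pooled covariance is rank deficient;",
                "refit with a positive `ridge`"))
  }
  whiten <- e2$vectors %*% diag(1 / sqrt(e2$values)) %*% t(e2$vectors)
  ew <- eigen(whiten %*% R1 %*% whiten, symmetric = TRUE)
  ord <- order(ew$values, decreasing = TRUE)
  filters <- whiten %*% ew$vectors[, ord, drop = FALSE]
  rownames(filters) <- class1$channel_labels
  structure(list(filters = filters, eigenvalues = ew$values[ord],
                 band = band,
                 class_labels = c(paste0(class1$condition, ".", class1$hand),
                                  paste0(class2$condition, ".", class2$hand)),
                 channel_labels = class1$channel_labels),
            class = "csp_model")
}

# average trace-normalized per-trial covariance, channels x channels
class_covariance <- function(epochs) {
  n_trials <- dim(epochs)[1]
  nch <- dim(epochs)[2]
  acc <- matrix(0, nch, nch)
  for (tr in seq_len(n_trials)) {
    s <- epochs[tr, , , drop = TRUE]
    if (is.null(dim(s))) s <- matrix(s, nrow = nch)
    cc <- tcrossprod(s) / ncol(s)
    trc <- sum(diag(cc))
    if (trc <= 0) abort("a trial has zero variance on every channel")
    acc <- acc + cc / trc
  }
  acc / n_trials
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters (%s vs %s), eigenvalues %.3g..%.3g\n",
              ncol(x$filters), x$class_labels[1], x$class_labels[2],
              x$eigenvalues[1], x$eigenvalues[length(x$eigenvalues)]))
  invisible(x)
}

#' @export
tidy.csp_model <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues)
}

#' Normalized log-variance CSP features
#'
#' Projects each trial on the first m and last m spatial filters and returns
#' the log of each component's variance share (variance normalized by the sum
#' over the 2m retained components).
#'
#' @param model A [fit_csp()] model.
#' @param trials A [trial_set()] on the model's channels.
#' @param m Number of filters kept from each end, `1 <= m <= channels/2`.
#' @return Tibble: `trial`, features `f1..f(2m)` in wide columns, plus
#'   `condition` and `hand` labels.
#' @export
csp_features <- function(model, trials, m) {
  stopifnot(inherits(model, "csp_model"), inherits(trials, "trial_set"))
  nch <- ncol(model$filters)
  if (m < 1 || m > nch / 2) {
    abort(sprintf("`m` must lie in [1, %d] for %d channels", nch %/% 2, nch))
  }
  sel <- c(seq_len(m), nch - seq_len(m) + 1L)
  W <- model$filters[, sel, drop = FALSE]
  n_trials <- dim(trials$epochs)[1]
  feats <- matrix(0, n_trials, 2 * m)
  for (tr in seq_len(n_trials)) {
    s <- matrix(trials$epochs[tr, , ], nrow = dim(trials$epochs)[2])
    proj <- crossprod(W, s)
    v <- apply(proj, 1, var)
    feats[tr, ] <- log(v / sum(v))
  }
  colnames(feats) <- paste0("f", seq_len(2 * m))
  out <- as_tibble(feats)
  out$trial <- seq_len(n_trials)
  out$condition <- trials$condition
  out$hand <- trials$hand
  out[, c("trial", paste0("f", seq_len(2 * m)), "condition", "hand")]
}

#' Fisher linear discriminant
#'
#' Two-class LDA: projection direction `w = Sw^{-1} (mu1 - mu2)` maximizing
#' the between- over within-class scatter, with the decision threshold at the
#' midpoint of the projected class means.
#'
#' @param features Numeric matrix or data frame of feature rows.
#' @param labels Vector with exactly two distinct values.
#' @param shrinkage Convex shrinkage of the pooled within-class scatter toward
#'   its diagonal mean, in `[0, 1)` (default 0; raise it if the scatter is
#'   singular).
#' @return An `lda_fisher` object with `w`, `threshold`, `classes` (first
#'   class is predicted when the projection exceeds the threshold).
#' @export
fit_lda <- function(features, labels, shrinkage = 0) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  classes <- unique(labels)
  if (length(classes) != 2) abort("exactly two classes are required")
  X1 <- X[labels == classes[1], , drop = FALSE]
  X2 <- X[labels == classes[2], , drop = FALSE]
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  Sw <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) /
    (nrow(X) - 2)
  if (shrinkage > 0) {
    Sw <- (1 - shrinkage) * Sw + shrinkage * mean(diag(Sw)) * diag(ncol(X))
  }
  w <- tryCatch(solve(Sw, mu1 - mu2), error = function(e) {
    abort("within-class scatter is singular; refit with `shrinkage` > 0")
  })
  threshold <- sum(w * (mu1 + mu2)) / 2
  structure(list(w = w, threshold = threshold, classes = classes),
            class = "lda_fisher")
}

#' Predict class labels from a Fisher discriminant
#'
#' @param object An [fit_lda()] model.
#' @param newdata Feature matrix/data frame with the training columns.
#' @param ... Unused.
#' @return Vector of predicted labels.
#' @export
predict.lda_fisher <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  proj <- drop(X %*% object$w)
  ifelse(proj > object$threshold, object$classes[1], object$classes[2])
}

feature_cols <- function(df) {
  as.matrix(df[, grep("^f[0-9]+$", names(df)), drop = FALSE])
}

#' Repeated stratified k-fold cross-validation of sub-band CSP + LDA
#'
#' Left- vs right-hand classification with sub-band CSP features: within each
#' training fold a CSP model is fitted per band (never on test trials, so
#' there is no leakage), normalized log-variance features of the first and
#' last `m` filters are concatenated over bands, and a Fisher LDA is trained
#' and evaluated on the held-out fold. Folds are stratified by class and
#' reshuffled on every repeat from the given seed.
#'
#' @param trials_left,trials_right [trial_set()] objects (one class each),
#'   already cropped to the classification window.
#' @param bands List of [band_definition()] sub-bands (the filter bank).
#' @param m Filters kept per end and per band.
#' @param k Folds (default 10).
#' @param repeats Number of shuffled repetitions.
#' @param seed Integer seed driving all shuffles.
#' @param shrinkage Passed to [fit_lda()].
#' @return A `cv_result`: tibble of per-repeat accuracies with attributes;
#'   see `glance()`.
#' @export
cross_validate <- function(trials_left, trials_right,
                           bands = default_bands()$classification,
                           m = 1, k = 10, repeats = 100, seed = 1L,
                           shrinkage = 0) {
  n1 <- dim(trials_left$epochs)[1]
  n2 <- dim(trials_right$epochs)[1]
  if (k > min(n1, n2)) abort(sprintf("k = %d exceeds the %d trials of a class",
                                     k, min(n1, n2)))
  filt_l <- lapply(bands, function(b) bandpass_trials(trials_left, b))
  filt_r <- lapply(bands, function(b) bandpass_trials(trials_right, b))
  acc <- numeric(repeats)
  for (rep_i in seq_len(repeats)) {
    set.seed(spawn_seed(seed, rep_i))
    fold1 <- sample(rep_len(seq_len(k), n1))
    fold2 <- sample(rep_len(seq_len(k), n2))
    correct <- 0L
    total <- 0L
    for (fold in seq_len(k)) {
      tr1 <- which(fold1 != fold); te1 <- which(fold1 == fold)
      tr2 <- which(fold2 != fold); te2 <- which(fold2 == fold)
      train_feats <- NULL; test_feats <- NULL
      for (b in seq_along(bands)) {
        csp <- fit_csp(subset_trials(filt_l[[b]], tr1),
                       subset_trials(filt_r[[b]], tr2), band = bands[[b]])
        ftr <- rbind(
          feature_cols(csp_features(csp, subset_trials(filt_l[[b]], tr1), m)),
          feature_cols(csp_features(csp, subset_trials(filt_r[[b]], tr2), m)))
        fte <- rbind(
          feature_cols(csp_features(csp, subset_trials(filt_l[[b]], te1), m)),
          feature_cols(csp_features(csp, subset_trials(filt_r[[b]], te2), m)))
        train_feats <- cbind(train_feats, ftr)
        test_feats <- cbind(test_feats, fte)
      }
      train_lab <- rep(c("left", "right"), c(length(tr1), length(tr2)))
      test_lab <- rep(c("left", "right"), c(length(te1), length(te2)))
      lda <- fit_lda(train_feats, train_lab, shrinkage = shrinkage)
      pred <- predict(lda, test_feats)
      correct <- correct + sum(pred == test_lab)
      total <- total + length(test_lab)
    }
    acc[rep_i] <- correct / total
  }
  structure(tibble(rep = seq_len(repeats), accuracy = acc),
            class = c("cv_result", class(tibble())),
            m = m, k = k, bands = bands, seed = seed)
}

subset_trials <- function(trials, idx) {
  trial_set(trials$epochs[idx, , , drop = FALSE], trials$time_axis,
            trials$condition, trials$hand, trials$fs, trials$channel_labels,
            trials$subject_id)
}

#' @export
glance.cv_result <- function(x, ...) {
  tibble(mean_accuracy = mean(x$accuracy), sd_accuracy = sd(x$accuracy),
         repeats = nrow(x), k = attr(x, "k"), m = attr(x, "m"))
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(attr(object, "m")),
                                       y = 100 * .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.4, fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = "m", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Sweep the number of retained CSP filter pairs
#'
#' Runs [cross_validate()] for every m in `m_range` and returns the sweep
#' table plus the accuracy-maximizing m (ties broken toward smaller m).
#'
#' @inheritParams cross_validate
#' @param m_range Candidate values of m.
#' @return List: `best_m`, `sweep` (tibble of m, mean and sd accuracy),
#'   `results` (per-m `cv_result`s).
#' @export
select_m <- function(trials_left, trials_right,
                     bands = default_bands()$classification,
                     m_range = 1:8, k = 10, repeats = 100, seed = 1L,
                     shrinkage = 0) {
  nch <- length(trials_left$channel_labels)
  m_range <- m_range[m_range <= nch / 2]
  if (length(m_range) == 0) abort("no admissible m for this channel count")
  results <- lapply(m_range, function(m) {
    cross_validate(trials_left, trials_right, bands = bands, m = m, k = k,
                   repeats = repeats, seed = seed, shrinkage = shrinkage)
  })
  sweep <- purrr::map2_dfr(results, m_range, function(r, m) {
    tibble(m = m, mean_accuracy = mean(r$accuracy),
           sd_accuracy = sd(r$accuracy))
  })
  best <- sweep$m[which.max(sweep$mean_accuracy)]  # which.max takes first tie
  list(best_m = best, sweep = sweep, results = results)
}
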