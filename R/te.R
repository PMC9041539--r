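#' Embedding and estimator parameters for transfer entropy
#'
#' @param d Sink embedding dimension (>= 1).
#' @param tau Embedding delay in samples (>= 1).
#' @param u Prediction horizon in samples (default 1).
#' @param k Neighbour count of the Kraskov estimator (default 4).
#' @param theiler Theiler exclusion window in samples (default 1): points
#'   closer in time than this within the same trial are never counted as
#'   neighbours, removing autocorrelation bias from the density estimates.
#' @param m Source embedding dimension; defaults to `d`.
#' @return An `embedding_params` list.
#' @export
embedding_params <- function(d = 1L, tau = 1L, u = 1L, k = 4L, theiler = 1L,
                             m = d) {
  stopifnot(d >= 1, tau >= 1, u >= 1, k >= 1, theiler >= 0, m >= 1)
  structure(list(d = as.integer(d), tau = as.integer(tau), u = as.integer(u),
                 k = as.integer(k), theiler = as.integer(theiler),
                 m = as.integer(m)),
            class = "embedding_params")
}

#' Select an embedding delay from autocorrelation decay
#'
#' Returns the first lag at which the autocorrelation function drops below
#' 1/e, bounded to `[1, max_lag]` — a standard fast proxy for the decorrelation
#' time of the series.
#'
#' @param x Numeric series, length >= 100.
#' @param max_lag Upper bound on the returned delay (default 20).
#' @return Integer delay in samples.
#' @export
select_delay <- function(x, max_lag = 20L) {
  if (length(x) < 100) abort("series must have length >= 100")
  if (sd(x) == 0) abort("constant series has no autocorrelation structure")
  a <- drop(acf(x, lag.max = max_lag, plot = FALSE)$acf)[-1]
  below <- which(a < exp(-1))
  if (length(below) == 0) return(as.integer(max_lag))
  max(1L, as.integer(below[1]))
}

#' Select an embedding dimension with Cao's method
#'
#' Computes Cao's E1 and E2 statistics (mean ratios of nearest-neighbour
#' distances when the embedding is extended by one dimension). E2 stays near 1
#' at every dimension for a purely stochastic series — such a series has no
#' deterministic structure to unfold, so dimension 1 is returned. Otherwise
#' the smallest d at which E1 saturates (`E1(d)/E1(d+1) > 0.95`) is returned,
#' capped at `d_max`. Both statistics are attached as attributes.
#'
#' @param x Numeric series.
#' @param tau Embedding delay (e.g. from [select_delay()]).
#' @param d_max Cap on the dimension (default 10).
#' @param n_max At most this many points are used (evenly subsampled) to keep
#'   the quadratic neighbour search cheap.
#' @return Integer dimension with attributes `E1` and `E2`.
#' @export
select_dimension <- function(x, tau, d_max = 10L, n_max = 1000L) {
  if (length(x) < 10 * (d_max + 2) * tau) {
    abort(sprintf("series too short: need at least %d samples for d_max = %d",
                  10 * (d_max + 2) * tau, d_max))
  }
  if (length(x) > n_max) {
    # subsampling stretches the sample spacing; rescale tau to the units of
    # the reduced series
    f <- n_max / length(x)
    x <- x[as.integer(round(seq(1L, length(x), length.out = n_max)))]
    tau <- max(1L, as.integer(round(tau * f)))
  }
  E <- cpp_cao(as.numeric(x), as.integer(tau), as.integer(d_max + 1L))
  E1 <- E[-1, 1] / E[-nrow(E), 1]          # E1(d), d = 1..d_max+1
  E2 <- E[-1, 2] / E[-nrow(E), 2]
  if (max(abs(E2[seq_len(d_max)] - 1)) < 0.2) {
    d <- 1L                                # stochastic: E2 flat at 1
  } else {
    ratio <- E1[-length(E1)] / E1[-1]      # E1(d)/E1(d+1), d = 1..d_max
    d <- which(ratio > 0.95)
    d <- if (length(d) == 0) as.integer(d_max) else min(as.integer(d[1]), d_max)
  }
  attr(d, "E1") <- E1
  attr(d, "E2") <- E2
  d
}

# delay-embed one trial: returns xf (future), xp (sink past), yp (source
# past) blocks plus time indices, or NULL if the trial is too short
embed_trial <- function(x, y, p) {
  n <- length(x)
  first <- max((p$d - 1L) * p$tau, (p$m - 1L) * p$tau) + 1L
  last <- n - p$u
  if (last < first + 1L) return(NULL)
  t_idx <- first:last
  xf <- matrix(x[t_idx + p$u], ncol = 1)
  xp <- vapply(0:(p$d - 1L), function(j) x[t_idx - j * p$tau],
               numeric(length(t_idx)))
  yp <- vapply(0:(p$m - 1L), function(j) y[t_idx - j * p$tau],
               numeric(length(t_idx)))
  list(xf = xf, xp = matrix(xp, ncol = p$d), yp = matrix(yp, ncol = p$m),
       t_idx = t_idx)
}

standardize_cols <- function(m) {
  s <- apply(m, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(m, 2, colMeans(m)), 2, s, "/")
}

#' k-nearest-neighbour transfer entropy
#'
#' Estimates the transfer entropy TE(Y -> X) in nats — the information the
#' past of the source Y adds about the next value of the sink X beyond X's
#' own past — via the Kraskov-style k-nearest-neighbour estimator of the
#' four-entropy decomposition (equivalently, the conditional mutual
#' information `I(x_{t+u}; y_t^m | x_t^d)` in its digamma form). Neighbour
#' searches use the max-norm after per-dimension standardization, with a
#' Theiler window excluding temporally adjacent points. Inputs may be single
#' series or trial ensembles (matrices with one row per trial); ensembles are
#' embedded per trial and pooled before the neighbour search, with the
#' Theiler exclusion applied within trials only.
#'
#' @param x Sink: numeric vector, or trials x samples matrix.
#' @param y Source, same shape as `x`.
#' @param params An [embedding_params()].
#' @param max_points Cap on pooled embedded points (deterministic even
#'   subsample) to bound the quadratic neighbour search.
#' @return TE estimate in nats (a single number, can be slightly negative by
#'   estimator noise under independence).
#' @export
#' @examples
#' p <- generate_coupled_ar(800, c_strength = 1, seed = 2)
#' te_knn(p$y, p$x, embedding_params(d = 1, tau = 1))
te_knn <- function(x, y, params = embedding_params(), max_points = 4000L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (!all(dim(x) == dim(y))) abort("`x` and `y` must have identical shape")
  p <- params
  blocks <- purrr::compact(lapply(seq_len(nrow(x)), function(tr) {
    b <- embed_trial(x[tr, ], y[tr, ], p)
    if (!is.null(b)) b$trial <- tr
    b
  }))
  if (length(blocks) == 0) {
    abort(sprintf("series too short after embedding: need > %d samples",
                  max((p$d - 1L) * p$tau, (p$m - 1L) * p$tau) + p$u + 1L))
  }
  xf <- do.call(rbind, lapply(blocks, `[[`, "xf"))
  xp <- do.call(rbind, lapply(blocks, `[[`, "xp"))
  yp <- do.call(rbind, lapply(blocks, `[[`, "yp"))
  trial <- unlist(lapply(blocks, function(b) rep(b$trial, length(b$t_idx))))
  t_idx <- unlist(lapply(blocks, `[[`, "t_idx"))
  n <- nrow(xf)
  if (n <= 10 * p$k) {
    abort(sprintf("only %d embedded points; need more than %d for k = %d",
                  n, 10 * p$k, p$k))
  }
  if (n > max_points) {
    keep <- unique(as.integer(round(seq(1, n, length.out = max_points))))
    xf <- xf[keep, , drop = FALSE]; xp <- xp[keep, , drop = FALSE]
    yp <- yp[keep, , drop = FALSE]
    trial <- trial[keep]; t_idx <- t_idx[keep]
  }
  cpp_ksg_cmi(standardize_cols(xf), standardize_cols(xp), standardize_cols(yp),
              p$k, p$theiler, as.integer(trial), as.integer(t_idx))
}

#' Directed transfer-entropy matrix over a montage
#'
#' Band-pass filters the trials, crops them to the requested window, and
#' estimates TE for every ordered pair of distinct channels by trial-ensemble
#' [te_knn()]. Embedding parameters are selected per sink channel on the
#' concatenated window data (delay by autocorrelation decay, dimension by
#' Cao's criterion) unless supplied; the source embedding uses the sink's
#' parameters.
#'
#' @param trials A [trial_set()] containing all requested channels.
#' @param band [band_definition()].
#' @param window Either `c(t0, t1)` in seconds or one of `"mi"` (0-10 s) and
#'   `"baseline"` (-2-0 s).
#' @param channels Montage to analyse (default the nine-channel montage).
#' @param params Optional [embedding_params()] used for every channel; if
#'   `NULL`, selected per channel with `d` capped at `d_max`.
#' @param d_max Cap on the selected embedding dimension.
#' @param max_points Passed to [te_knn()].
#' @return A `te_matrix`: `values` is a source x sink matrix in nats with an
#'   undefined (NA) diagonal; carries band/condition/hand/window metadata and
#'   the per-channel embedding table.
#' @export
te_matrix <- function(trials, band, window = "mi",
                      channels = analysis_montage(), params = NULL,
                      d_max = 3L, max_points = 2000L) {
  stopifnot(inherits(trials, "trial_set"))
  missing_ch <- setdiff(channels, trials$channel_labels)
  if (length(missing_ch) > 0) {
    abort(sprintf("channel(s) missing from the trials: %s",
                  paste(missing_ch, collapse = ", ")))
  }
  if (is.character(window)) {
    window <- switch(window, mi = c(0, 10), baseline = c(-2, 0),
                     abort("window must be 'mi', 'baseline' or c(t0, t1)"))
    window[2] <- min(window[2], max(trials$time_axis) + 1 / trials$fs)
  }
  win_label <- sprintf("[%g, %g) s", window[1], window[2])
  filt <- bandpass_trials(trials, band)
  filt <- crop_trials(filt, window)
  ch_idx <- match(channels, filt$channel_labels)
  n_trials <- dim(filt$epochs)[1]

  emb <- vector("list", length(channels))
  for (i in seq_along(channels)) {
    if (!is.null(params)) {
      emb[[i]] <- params
    } else {
      series <- as.vector(t(filt$epochs[, ch_idx[i], ]))
      tau <- select_delay(series)
      d <- tryCatch(as.integer(select_dimension(series, tau, d_max = d_max)),
                    error = function(e) 1L)
      emb[[i]] <- embedding_params(d = d, tau = tau)
    }
  }
  vals <- matrix(NA_real_, length(channels), length(channels),
                 dimnames = list(channels, channels))
  for (snk in seq_along(channels)) {
    xs <- matrix(filt$epochs[, ch_idx[snk], ], nrow = n_trials)
    for (src in seq_along(channels)) {
      if (src == snk) next
      ys <- matrix(filt$epochs[, ch_idx[src], ], nrow = n_trials)
      vals[src, snk] <- te_knn(xs, ys, emb[[snk]], max_points = max_points)
    }
  }
  structure(list(values = vals, band = band, condition = trials$condition,
                 hand = trials$hand, window = win_label,
                 n_trials = n_trials,
                 embedding = tibble(
                   channel = channels,
                   d = vapply(emb, `[[`, integer(1), "d"),
                   tau = vapply(emb, `[[`, integer(1), "tau"))),
            class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat(sprintf("<te_matrix> %s band, %s/%s, window %s, %d trials (nats)\n",
              x$band$name, x$condition, x$hand, x$window, x$n_trials))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
tidy.te_matrix <- function(x, ...) {
  labs <- rownames(x$values)
  df <- expand.grid(source = labs, sink = labs, stringsAsFactors = FALSE)
  df$te <- as.vector(x$values)
  out <- as_tibble(df[df$source != df$sink, ])
  out$band <- x$band$name
  out$condition <- x$condition
  out$hand <- x$hand
  out$window <- x$window
  out
}

#' @export
autoplot.te_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sink, y = .data$source,
                                   fill = .data$te)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(title = sprintf("TE (nats), %s band, %s/%s, %s",
                                  object$band$name, object$condition,
                                  object$hand, object$window),
                  x = "sink", y = "source", fill = "TE") +
    ggplot2::theme_minimal()
}

#' Relative transfer entropy: task window minus baseline
#'
#' Element-wise subtraction of the fixation-stage TE matrix from the
#' MI-stage matrix, the baseline-normalized connectivity measure. Negative
#' values (connectivity below baseline) are kept.
#'
#' @param te_task,te_baseline [te_matrix()] results with matching montage,
#'   band, condition and hand.
#' @return A `te_matrix` with window label `"relative"`.
#' @export
relative_te <- function(te_task, te_baseline) {
  stopifnot(inherits(te_task, "te_matrix"), inherits(te_baseline, "te_matrix"))
  if (!identical(rownames(te_task$values), rownames(te_baseline$values))) {
    abort("montage mismatch between task and baseline matrices")
  }
  if (!identical(te_task$band$name, te_baseline$band$name) ||
      !identical(te_task$condition, te_baseline$condition) ||
      !identical(te_task$hand, te_baseline$hand)) {
    abort("band/condition/hand must match between task and baseline")
  }
  out <- te_task
  out$values <- te_task$values - te_baseline$values
  out$window <- "relative"
  out
}
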