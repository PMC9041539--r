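#' Wilcoxon signed-rank test with an exact tied-rank null
#'
#' Paired two-sided signed-rank test. Zero differences are dropped (their
#' count is reported); absolute differences are ranked with ties mid-ranked.
#' For n <= 25 retained pairs the null distribution of the positive-rank sum
#' is computed exactly by convolution over the 2^n equiprobable sign
#' assignments (mid-ranks are doubled to integers first, so ties are handled
#' exactly rather than by approximation); for larger n a normal approximation
#' with continuity and tie corrections is used.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @return One-row tibble: `statistic` (positive-rank sum W), `p.value`
#'   (two-sided), `n` (pairs used), `n_zero` (zero differences dropped),
#'   `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 0, 0, 0))
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  d <- a - b
  d <- d[is.finite(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warn("all paired differences are zero; p = 1")
    return(tibble(statistic = 0, p.value = 1, n = 0L, n_zero = n_zero,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    p <- signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  tibble(statistic = w, p.value = p, n = n, n_zero = n_zero, method = method)
}

# exact two-sided p for positive-rank sum w given the (possibly tied) ranks:
# distribution of sum over random sign assignments via integer convolution on
# doubled ranks.
signed_rank_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  # counts[s + 1] = number of sign assignments with doubled rank-sum s
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (x in r2) {
    shifted <- c(numeric(x), counts[seq_len(length(counts) - x)])
    counts <- counts + shifted
  }
  counts <- counts / sum(counts)
  w2 <- as.integer(round(2 * w))
  p_le <- sum(counts[seq_len(w2 + 1)])
  p_ge <- sum(counts[(w2 + 1):length(counts)])
  min(1, 2 * min(p_le, p_ge))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p-values: sorted p(i) are scaled by
#' m/i, monotonicity is enforced from the largest rank down, values are capped
#' at 1 and returned in the original order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
fdr_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Contrast relative transfer entropy between two conditions across subjects
#'
#' For every directed channel pair, the per-subject relative-TE values of
#' condition A and condition B are compared with the two-sided Wilcoxon
#' signed-rank test; raw p-values are Benjamini-Hochberg adjusted within the
#' family of all directed pairs of this band x hand x contrast panel, and an
#' edge is retained when its adjusted p falls below `alpha`. The reported
#' direction is the sign of the median paired difference (which condition is
#' larger), attached after the two-sided retention decision.
#'
#' @param te_a,te_b Lists of [te_matrix()] results (or plain matrices), one
#'   per subject, same subjects in the same order, same montage.
#' @param alpha Retention threshold on the adjusted p-value.
#' @param contrast Label for the contrast (e.g. `"rmMI-tMI"`).
#' @return A `connectivity_contrast`: a tibble with one row per directed pair
#'   (`source`, `sink`, `statistic`, `p.value`, `p.adjusted`, `direction`,
#'   `retained`) carrying band/hand/contrast/alpha attributes.
#' @export
contrast_conditions <- function(te_a, te_b, alpha = 0.05, contrast = "A-B") {
  ma <- lapply(te_a, te_values)
  mb <- lapply(te_b, te_values)
  if (length(ma) != length(mb)) abort("subject lists must have equal length")
  if (length(ma) < 5) abort("need at least 5 subjects")
  labs <- rownames(ma[[1]])
  for (m in c(ma, mb)) {
    if (!identical(rownames(m), labs)) abort("montage mismatch between subjects")
  }
  meta_a <- te_meta(te_a[[1]])
  meta_b <- te_meta(te_b[[1]])
  if (!is.null(meta_a$band) && !is.null(meta_b$band) &&
      !identical(meta_a$band$name, meta_b$band$name)) {
    abort("band mismatch between the two condition lists")
  }
  pairs <- expand.grid(source = labs, sink = labs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$sink, , drop = FALSE]
  pairs <- pairs[order(match(pairs$source, labs), match(pairs$sink, labs)), ]
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    va <- vapply(ma, function(m) m[pairs$source[i], pairs$sink[i]], numeric(1))
    vb <- vapply(mb, function(m) m[pairs$source[i], pairs$sink[i]], numeric(1))
    wt <- suppressWarnings(wilcoxon_signed_rank(va, vb))
    med <- median(va - vb)
    tibble(source = pairs$source[i], sink = pairs$sink[i],
           statistic = wt$statistic, p.value = wt$p.value,
           direction = if (med > 0) "A>B" else if (med < 0) "B>A" else "none")
  })
  res$p.adjusted <- fdr_adjust(res$p.value)
  res$retained <- res$p.adjusted < alpha
  structure(res,
            class = c("connectivity_contrast", class(res)),
            band = meta_a$band, hand = meta_a$hand, contrast = contrast,
            alpha = alpha, n_subjects = length(ma))
}

te_values <- function(x) {
  if (inherits(x, "te_matrix")) x$values else as.matrix(x)
}

te_meta <- function(x) {
  if (inherits(x, "te_matrix")) list(band = x$band, hand = x$hand)
  else list(band = NULL, hand = NULL)
}

#' @export
glance.connectivity_contrast <- function(x, ...) {
  tibble(
    contrast = attr(x, "contrast"),
    band = if (!is.null(attr(x, "band"))) attr(x, "band")$name else NA_character_,
    hand = attr(x, "hand") %||% NA_character_,
    n_subjects = attr(x, "n_subjects"),
    n_pairs = nrow(x),
    n_retained = sum(x$retained),
    alpha = attr(x, "alpha"),
    min_p_adjusted = min(x$p.adjusted)
  )
}

#' @export
tidy.connectivity_contrast <- function(x, ...) {
  out <- as_tibble(x)
  out$contrast <- attr(x, "contrast")
  out$hand <- attr(x, "hand") %||% NA_character_
  out$band <- if (!is.null(attr(x, "band"))) attr(x, "band")$name else NA_character_
  out
}

#' @export
autoplot.connectivity_contrast <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sink, y = .data$source,
                                   fill = .data$retained)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90", `TRUE` = "firebrick")) +
    ggplot2::labs(title = sprintf("%s (%s, %s): %d retained edges",
                                  attr(object, "contrast"),
                                  df$band[1], df$hand[1],
                                  sum(object$retained)),
                  x = "sink", y = "source") +
    ggplot2::theme_minimal()
}
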