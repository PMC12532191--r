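#' Multi-tau lag grid
#'
#' Quasi-logarithmic lag grid with `m` linear lags per octave: lags
#' 1..m at unit spacing, then each subsequent octave doubles the spacing.
#'
#' @param n_max largest lag (in bins) to include.
#' @param m linear lags per octave.
#' @return increasing integer vector of lags in bins.
#' @keywords internal
multitau_lags <- function(n_max, m = 16) {
  lags <- seq_len(min(m, n_max))
  spacing <- 2
  top <- m
  while (top < n_max) {
    nxt <- seq(top + spacing, min(2 * top, n_max), by = spacing)
    lags <- c(lags, nxt)
    top <- 2 * top
    spacing <- 2 * spacing
  }
  unique(lags[lags <= n_max])
}

# Exact normalized autocorrelation of one segment at the given bin lags:
# G(k) = mean(I_t * I_{t+k}) / (mean(I_{1..n-k}) * mean(I_{k+1..n})).
# The symmetric normalization makes G of a constant trace exactly 1 and is
# evaluated directly (no 2x rebinning), so it agrees with a brute-force
# evaluation of the estimator to machine precision at every lag.
segment_acf <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(k) {
    a <- x[1:(n - k)]
    b <- x[(k + 1):n]
    mean(a * b) / (mean(a) * mean(b))
  }, numeric(1))
}

#' Autocorrelation curve of an intensity trace
#'
#' Splits the trace into consecutive segments of `segment_length` seconds,
#' computes the normalized autocorrelation
#' `G(tau) = <I(t) I(t+tau)> / <I(t)>^2`
#' of each segment on a multi-tau (16 lags per octave) grid, and averages
#' over segments, recording the per-lag SD. Segments with a monotone
#' intensity drop greater than `bleach_drop` across the segment (assessed on
#' ten coarse chunks) are excluded as bleaching artifacts; zero-mean
#' segments are excluded with a warning.
#'
#' @param trace an [intensity_trace()] (or data.frame `time_s, counts`).
#' @param segment_length segment duration in s (default 20, matching a
#'   series of consecutive 20 s measurements).
#' @param max_lag largest lag in s (default `segment_length / 2`).
#' @param bleach_drop relative first-to-last chunk drop that triggers
#'   exclusion when the chunk trend is monotone decreasing.
#' @return object of class `acc`: list with `lag_s`, `G`, `sd`,
#'   `n_segments`, `excluded_segments`, `mean_intensity` (counts/s),
#'   `bin_time`.
#' @export
autocorrelate <- function(trace, segment_length = 20, max_lag = NULL,
                          bleach_drop = 0.2) {
  bin_time <- attr(trace, "bin_time")
  if (is.null(bin_time)) {
    stopifnot(is.data.frame(trace), nrow(trace) >= 2)
    bin_time <- trace$time_s[2] - trace$time_s[1]
  }
  x <- trace$counts
  seg_bins <- floor(segment_length / bin_time)
  n_seg <- floor(length(x) / seg_bins)
  if (n_seg < 1) stop("trace shorter than one segment")
  if (is.null(max_lag)) max_lag <- segment_length / 2
  lag_bins <- multitau_lags(min(seg_bins - 1, floor(max_lag / bin_time)))

  g_mat <- matrix(NA_real_, length(lag_bins), n_seg)
  excluded <- integer(0)
  for (s in seq_len(n_seg)) {
    seg <- x[((s - 1) * seg_bins + 1):(s * seg_bins)]
    if (mean(seg) == 0) {
      warning("segment ", s, " has zero mean; excluded")
      excluded <- c(excluded, s)
      next
    }
    if (bleach_segment(seg, bleach_drop)) {
      excluded <- c(excluded, s)
      next
    }
    g_mat[, s] <- segment_acf(seg, lag_bins)
  }
  used <- setdiff(seq_len(n_seg), excluded)
  if (length(used) == 0) stop("all segments excluded")
  g <- rowMeans(g_mat[, used, drop = FALSE])
  gsd <- if (length(used) > 1) apply(g_mat[, used, drop = FALSE], 1, sd)
         else rep(NA_real_, length(lag_bins))
  out <- list(lag_s = lag_bins * bin_time, G = g, sd = gsd,
              n_segments = length(used), excluded_segments = excluded,
              mean_intensity = mean(x) / bin_time, bin_time = bin_time)
  class(out) <- "acc"
  out
}

# TRUE when the segment shows a monotone bleaching-like drop: chunk means
# strongly anticorrelated with time and a first-to-last drop > threshold.
bleach_segment <- function(seg, drop_threshold) {
  n_chunks <- 10
  if (length(seg) < 2 * n_chunks) return(FALSE)
  chunk <- floor(length(seg) / n_chunks)
  means <- vapply(seq_len(n_chunks), function(i)
    mean(seg[((i - 1) * chunk + 1):(i * chunk)]), numeric(1))
  if (means[1] <= 0) return(FALSE)
  drop <- (means[1] - means[n_chunks]) / means[1]
  monotone <- suppressWarnings(cor(means, seq_len(n_chunks),
                                   method = "spearman"))
  isTRUE(drop > drop_threshold && !is.na(monotone) && monotone < -0.8)
}

#' Build an autocorrelation curve from precomputed values
#'
#' @param lag_s increasing lag times in s.
#' @param G autocorrelation values.
#' @param sd optional per-lag SD (used as fit weights).
#' @return object of class `acc`.
#' @export
acc_curve <- function(lag_s, G, sd = NULL) {
  stopifnot(length(lag_s) == length(G), !is.unsorted(lag_s))
  out <- list(lag_s = lag_s, G = G,
              sd = if (is.null(sd)) rep(NA_real_, length(G)) else sd,
              n_segments = 1L, excluded_segments = integer(0),
              mean_intensity = NA_real_, bin_time = NA_real_)
  class(out) <- "acc"
  out
}
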