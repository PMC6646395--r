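#' Moving-average smoothing of the order-parameter trace
#'
#' Centred moving average over a 400 ms window evaluated every 10 ms, the
#' preprocessing used before LFP-burst detection. Input samples must be at
#' 10 ms resolution or finer.
#'
#' @param x Numeric trace samples.
#' @param dt Sampling step of `x` (ms, <= `step_ms`).
#' @param window_ms Averaging window (ms). Default 400.
#' @param step_ms Output step (ms). Default 10.
#' @return A tibble with columns `t` (ms, relative to the start of `x`)
#'   and `value` (smoothed trace).
#' @export
smooth_trace <- function(x, dt, window_ms = 400, step_ms = 10) {
  if (dt > step_ms + 1e-12) stop("trace must be sampled at <= step_ms",
                                 call. = FALSE)
  n <- length(x)
  w <- as.integer(round(window_ms / dt))
  if (n < w) stop("trace shorter than the smoothing window", call. = FALSE)
  half <- w / 2
  stride <- max(1L, as.integer(round(step_ms / dt)))
  centers <- seq(from = ceiling(half) + 1, to = n - ceiling(half),
                 by = stride)
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, as.integer(centers - floor(half)))
  hi <- pmin(n, as.integer(centers + floor(half)))
  val <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  tibble::tibble(t = (centers - 1) * dt, value = val)
}

#' Dual percentile burst thresholds
#'
#' Upper (75th) and lower (65th) linear-interpolation percentiles of the
#' smoothed trace over the analysis window.
#'
#' @param trace Numeric vector (smoothed trace samples in the window).
#' @param probs Percentile pair (upper, lower). Default `c(0.75, 0.65)`.
#' @return Named numeric vector `c(upper =, lower =)`.
#' @export
percentile_thresholds <- function(trace, probs = c(0.75, 0.65)) {
  if (length(trace) == 0) stop("empty analysis window", call. = FALSE)
  q <- stats::quantile(trace, probs = probs, names = FALSE, type = 7)
  c(upper = q[1], lower = q[2])
}

#' Detect LFP bursts by dual-threshold crossing
#'
#' A burst opens at an upward crossing of the upper threshold (while no
#' burst is open) and closes at the next downward crossing of the lower
#' threshold. Bursts still open at the end of the trace are discarded, as
#' is any burst already open at its start.
#'
#' @param t Time stamps of the smoothed trace (ms or s, any unit).
#' @param value Smoothed trace samples.
#' @param upper,lower Thresholds with `upper >= lower`.
#' @return A tibble with columns `onset`, `offset`, `length` (in the units
#'   of `t`), one row per burst.
#' @export
detect_lfp_bursts <- function(t, value, upper, lower) {
  if (upper < lower) stop("require upper >= lower", call. = FALSE)
  stopifnot(length(t) == length(value))
  onsets <- numeric(0); offsets <- numeric(0)
  open <- FALSE; cur_on <- NA_real_
  for (i in seq_along(value)[-1]) {
    if (!open && value[i - 1] <= upper && value[i] > upper) {
      open <- TRUE; cur_on <- t[i]
    } else if (open && value[i - 1] >= lower && value[i] < lower) {
      onsets <- c(onsets, cur_on); offsets <- c(offsets, t[i])
      open <- FALSE
    }
  }
  tibble::tibble(onset = onsets, offset = offsets, length = offsets - onsets)
}

#' Burst-length statistics
#'
#' Mean and median burst length, the fraction of bursts shorter than a
#' cutoff, and a length histogram.
#'
#' @param bursts Tibble from [detect_lfp_bursts()] (or any data frame with
#'   a `length` column), lengths in seconds.
#' @param cutoff_s Cutoff (s) for the short-burst fraction. Default 5.
#' @param bin_s Histogram bin width (s). Default 1.
#' @return A list of class `burst_stats` with elements `n`, `mean`,
#'   `median`, `frac_short`, `cutoff_s` and `histogram` (tibble with
#'   `bin_lo`, `bin_hi`, `count`). With zero bursts the scalar statistics
#'   are NA (undefined), not zero.
#' @export
burst_statistics <- function(bursts, cutoff_s = 5, bin_s = 1) {
  len <- bursts$length
  if (length(len) == 0) {
    return(structure(list(n = 0L, mean = NA_real_, median = NA_real_,
                          frac_short = NA_real_, cutoff_s = cutoff_s,
                          histogram = tibble::tibble(bin_lo = numeric(0),
                                                     bin_hi = numeric(0),
                                                     count = integer(0))),
                     class = "burst_stats"))
  }
  breaks <- seq(0, max(len) + bin_s, by = bin_s)
  cnt <- table(cut(len, breaks, right = FALSE))
  structure(list(
    n = length(len),
    mean = mean(len),
    median = stats::median(len),
    frac_short = mean(len < cutoff_s),
    cutoff_s = cutoff_s,
    histogram = tibble::tibble(bin_lo = breaks[-length(breaks)],
                               bin_hi = breaks[-1],
                               count = as.integer(cnt))
  ), class = "burst_stats")
}

#' @export
print.burst_stats <- function(x, ...) {
  cat(sprintf("<burst_stats: %d bursts>\n", x$n))
  if (x$n > 0) {
    cat(sprintf("  mean %.3g s, median %.3g s, %.1f%% shorter than %g s\n",
                x$mean, x$median, 100 * x$frac_short, x$cutoff_s))
  }
  invisible(x)
}

#' Compare two burst-length samples
#'
#' Two-sided rank-based two-sample test (Mann-Whitney U by default, exact
#' permutation of the rank-sum statistic on request) for a difference in
#' burst-length distributions.
#'
#' @param lengths_a,lengths_b Numeric samples of burst lengths (nonempty).
#' @param method `"wilcox"` (default) or `"permutation"`.
#' @param n_perm Permutation count for `method = "permutation"`; if the
#'   number of distinct splits is smaller, full enumeration is used.
#' @return Two-sided p-value.
#' @export
compare_burst_lengths <- function(lengths_a, lengths_b,
                                  method = c("wilcox", "permutation"),
                                  n_perm = 10000) {
  method <- match.arg(method)
  if (length(lengths_a) == 0 || length(lengths_b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  if (method == "wilcox") {
    return(stats::wilcox.test(lengths_a, lengths_b, exact = FALSE)$p.value)
  }
  pooled <- c(lengths_a, lengths_b)
  rk <- rank(pooled)
  na <- length(lengths_a)
  obs <- sum(rk[seq_len(na)])
  mu <- na * (length(pooled) + 1) / 2
  n_comb <- choose(length(pooled), na)
  if (is.finite(n_comb) && n_comb <= n_perm) {
    idx <- utils::combn(length(pooled), na)
    stat <- colSums(matrix(rk[idx], nrow = na))
    p <- mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
  } else {
    stat <- replicate(n_perm, sum(sample(rk, na)))
    p <- (1 + sum(abs(stat - mu) >= abs(obs - mu) - 1e-9)) / (n_perm + 1)
  }
  min(1, p)
}
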