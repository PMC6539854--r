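#' Estimate the time lag between two signals by cross-correlation
#'
#' Maximizes the normalized (coefficient-form) cross-correlation over integer
#' sample shifts, so the estimate is invariant to amplitude scaling and
#' offsets of either signal. Positive lag means `y` trails `x`. Ties are
#' broken toward the smallest absolute lag.
#'
#' @param x,y Uniformly sampled [sampled_signal]s at the same rate.
#' @param max_lag Maximum absolute lag to search, s (default 2).
#' @return The lag in seconds, resolved to the sample grid.
#' @export
estimate_lag <- function(x, y, max_lag = 2) {
  stopifnot(inherits(x, "sampled_signal"), inherits(y, "sampled_signal"))
  assert_uniform(x, "estimate_lag"); assert_uniform(y, "estimate_lag")
  fx <- signal_rate(x); fy <- signal_rate(y)
  if (abs(fx - fy) > 1e-6 * fx) {
    stop("signals must share one sampling rate; resample first", call. = FALSE)
  }
  xv <- x$values; yv <- y$values
  L <- as.integer(round(max_lag * fx))
  nmin <- min(length(xv), length(yv))
  if (nmin <= L + 2) {
    stop("overlap too short for the requested max_lag", call. = FALSE)
  }
  ks <- (-L):L
  cs <- vapply(ks, function(k) {
    if (k >= 0) {
      a <- xv[1:(length(xv) - k)]
      b <- yv[(1 + k):length(yv)]
    } else {
      a <- xv[(1 - k):length(xv)]
      b <- yv[1:(length(yv) + k)]
    }
    m <- min(length(a), length(b))
    a <- a[1:m]; b <- b[1:m]
    if (m < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }, numeric(1))
  best <- ks[order(-cs, abs(ks))][1]
  best / fx
}

#' Shift and trim a signal pair to its common support
#'
#' Applies an integer-sample lag (as estimated by [estimate_lag()]) and trims
#' both signals to equal length on a shared time base.
#'
#' @param x,y Uniformly sampled [sampled_signal]s at the same rate.
#' @param lag Lag in seconds (positive: `y` trails `x`).
#' @return A list with elements `x` and `y`, equal-length signals on `x`'s
#'   (trimmed) time base.
#' @export
align_pair <- function(x, y, lag) {
  stopifnot(inherits(x, "sampled_signal"), inherits(y, "sampled_signal"))
  fs <- signal_rate(x)
  k <- as.integer(round(lag * fs))
  nx <- length(x$values); ny <- length(y$values)
  ix0 <- 1L + max(-k, 0L)
  iy0 <- 1L + max(k, 0L)
  m <- min(nx - (ix0 - 1L), ny - (iy0 - 1L))
  if (m < 1) stop("empty overlap after applying the lag", call. = FALSE)
  tt <- x$timestamps[ix0:(ix0 + m - 1L)]
  list(
    x = sampled_signal(tt, x$values[ix0:(ix0 + m - 1L)], x$axis, x$quantity,
                       x$nominal_rate),
    y = sampled_signal(tt, y$values[iy0:(iy0 + m - 1L)], y$axis, y$quantity,
                       y$nominal_rate)
  )
}

#' Normalized root-mean-square error
#'
#' RMSE of `test - reference` divided by the reference signal's amplitude
#' range, in percent. Lower is better agreement.
#'
#' @param reference,test Equal-length [sampled_signal]s (or bare numeric
#'   vectors) of aligned samples; the reference plays the
#'   inertial-sensor role and supplies the normalizing range.
#' @return NRMSE in percent.
#' @export
nrmse <- function(reference, test) {
  r <- if (inherits(reference, "sampled_signal")) reference$values else as.numeric(reference)
  s <- if (inherits(test, "sampled_signal")) test$values else as.numeric(test)
  if (length(r) != length(s)) stop("signals must have equal length", call. = FALSE)
  if (length(r) < 2) stop("need at least 2 samples", call. = FALSE)
  rng <- max(r) - min(r)
  if (rng <= 0) stop("reference amplitude range is zero; NRMSE undefined", call. = FALSE)
  100 * sqrt(mean((s - r)^2)) / rng
}

#' Zero-lag cross-correlation coefficient
#'
#' Pearson correlation of the aligned sample pairs; ~1 indicates near-perfect
#' signal similarity.
#'
#' @param x,y Equal-length [sampled_signal]s or numeric vectors, both
#'   non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
xcor_zero_lag <- function(x, y) {
  a <- if (inherits(x, "sampled_signal")) x$values else as.numeric(x)
  b <- if (inherits(y, "sampled_signal")) y$values else as.numeric(y)
  if (length(a) != length(b)) stop("signals must have equal length", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant signal", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Agreement statistics for an aligned device pair
#'
#' Convenience wrapper: applies the lag, trims to common support, and
#' computes NRMSE and zero-lag cross-correlation.
#'
#' @param reference,test Uniformly sampled [sampled_signal]s at one rate.
#' @param lag Lag in seconds (e.g. from [estimate_lag()]); default 0.
#' @return An object of class `agreement_result` with fields `nrmse_pct`,
#'   `xcor`, `lag_s`, `n_samples`.
#' @export
agreement <- function(reference, test, lag = 0) {
  al <- align_pair(reference, test, lag)
  structure(list(nrmse_pct = nrmse(al$x, al$y),
                 xcor = xcor_zero_lag(al$x, al$y),
                 lag_s = lag, n_samples = length(al$x$values)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement> NRMSE %.2f%%, Xcor %.3f, lag %.3f s (n = %d)\n",
              x$nrmse_pct, x$xcor, x$lag_s, x$n_samples))
  invisible(x)
}

#' Mean with a t-based 95% confidence interval
#'
#' Used to aggregate per-trial NRMSE and Xcor values within a test condition.
#' The t multiplier (not 1.96) is used because per-condition sample sizes are
#' small.
#'
#' @param values Numeric vector, length >= 2.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `summary_ci` with `mean`, `ci_low`, `ci_high`,
#'   `n`.
#' @export
summarize_ci <- function(values, conf = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval", call. = FALSE)
  m <- mean(values)
  hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  structure(list(mean = m, ci_low = m - hw, ci_high = m + hw, n = n),
            class = "summary_ci")
}

#' @export
print.summary_ci <- function(x, ...) {
  cat(sprintf("%.3f (%.3f, %.3f), n = %d\n", x$mean, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' Differences `a - b` of paired measurements; the limits of agreement are
#' the mean difference plus/minus 1.96 times the sample standard deviation of
#' the differences — the interval expected to contain 95% of method
#' disagreements.
#'
#' @param a,b Equal-length numeric vectors of paired measurements (e.g.
#'   sensor-derived vs stopwatch task times), n >= 2.
#' @return An object of class `bland_altman_result` with `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n_pairs`, and the per-pair `means`
#'   and `diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired vectors must have equal length", call. = FALSE)
  n <- length(a)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(mean_diff = md, sd_diff = s,
                 loa_low = md - 1.96 * s, loa_high = md + 1.96 * s,
                 n_pairs = n, means = (a + b) / 2, diffs = d),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("<bland_altman> mean diff %.3f, LoA [%.3f, %.3f], n = %d\n",
              x$mean_diff, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' Two-sided two-sample Student t-test
#'
#' Pooled-variance Student form by default (matching the classical name);
#' Welch's unequal-variance form by flag. When both groups are degenerate
#' (zero variance) with equal means the contract is `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param var_equal Pooled-variance Student form (default `TRUE`); `FALSE`
#'   for Welch.
#' @return A list with `t`, `p` and `df`.
#' @export
two_sample_ttest <- function(group_a, group_b, var_equal = TRUE) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, p = 1, df = length(a) + length(b) - 2))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = length(a) + length(b) - 2))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}
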