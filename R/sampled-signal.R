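#' Construct a sampled signal
#'
#' The universal currency of the pipeline: one time-stamped scalar channel
#' with body-axis and physical-quantity metadata. Timestamps must be strictly
#' increasing and the same length as the values.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param values Numeric vector of samples (m, m/s or m/s^2 depending on
#'   `quantity`).
#' @param axis Body axis: `"VT"` (vertical), `"AP"` (anterior-posterior) or
#'   `"ML"` (medio-lateral).
#' @param quantity One of `"displacement"`, `"velocity"`, `"acceleration"`.
#' @param nominal_rate Nominal sampling rate in Hz (informational; the actual
#'   rate is derived from the timestamps). `NA` when unknown.
#'
#' @return An object of class `sampled_signal`: a list with elements
#'   `timestamps`, `values`, `axis`, `quantity`, `nominal_rate`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1 / 30)
#' s <- sampled_signal(t, sin(2 * pi * t), "VT", "displacement", 30)
sampled_signal <- function(timestamps, values, axis = c("VT", "AP", "ML"),
                           quantity = c("displacement", "velocity", "acceleration"),
                           nominal_rate = NA_real_) {
  axis <- match.arg(axis)
  quantity <- match.arg(quantity)
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (length(timestamps) != length(values)) {
    stop("timestamps and values must have the same length", call. = FALSE)
  }
  if (anyNA(timestamps) || anyNA(values)) {
    stop("sampled_signal does not accept NA/NaN samples", call. = FALSE)
  }
  if (length(timestamps) >= 2 && any(diff(timestamps) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  structure(
    list(timestamps = timestamps, values = values, axis = axis,
         quantity = quantity, nominal_rate = as.numeric(nominal_rate)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  n <- length(x$values)
  span <- if (n >= 2) diff(range(x$timestamps)) else 0
  cat(sprintf("<sampled_signal> %s %s: %d samples over %.2f s (rate ~%.1f Hz)\n",
              x$axis, x$quantity, n, span,
              if (n >= 2) (n - 1) / span else NA_real_))
  invisible(x)
}

# Effective mean sampling rate from the timestamps.
signal_rate <- function(sig) {
  n <- length(sig$timestamps)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  (n - 1) / (sig$timestamps[n] - sig$timestamps[1])
}

# Uniform-sampling check: all gaps equal to the mean gap within tol (relative).
is_uniform <- function(sig, tol = 1e-6) {
  d <- diff(sig$timestamps)
  if (length(d) == 0) return(TRUE)
  dt <- mean(d)
  all(abs(d - dt) <= tol * dt)
}

assert_uniform <- function(sig, what = "operation") {
  if (!is_uniform(sig)) {
    stop(sprintf("%s requires uniform sampling; resample first (see resample_uniform)",
                 what), call. = FALSE)
  }
  invisible(sig)
}

units_of <- function(quantity) {
  switch(quantity,
         displacement = "m", velocity = "m/s", acceleration = "m/s^2")
}

#' Resample a signal onto a uniform grid
#'
#' Linearly interpolates the samples onto the grid `t0 + k / target_rate`
#' covering the original time span, anchored at the first timestamp. This is
#' the first step of the pipeline for both the jittered ~30 Hz position
#' channel and the 128 Hz inertial channel.
#'
#' @param signal A [sampled_signal].
#' @param target_rate Output sampling rate in Hz.
#'
#' @return A [sampled_signal] on the uniform grid, same axis/quantity.
#'   A warning is raised when `target_rate` exceeds twice the effective input
#'   rate (upsampling beyond the Nyquist support risks aliasing artifacts).
#' @export
resample_uniform <- function(signal, target_rate) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1 || target_rate <= 0) {
    stop("target_rate must be a positive scalar", call. = FALSE)
  }
  n <- length(signal$values)
  if (n < 2) stop("resampling needs at least 2 samples", call. = FALSE)
  eff <- signal_rate(signal)
  if (target_rate > 2 * eff) {
    warning(sprintf("target_rate %.3g Hz exceeds twice the effective input rate %.3g Hz (aliasing risk)",
                    target_rate, eff), call. = FALSE)
  }
  t0 <- signal$timestamps[1]
  tn <- signal$timestamps[n]
  k <- 0:floor((tn - t0) * target_rate + 1e-9)
  tout <- t0 + k / target_rate
  # rule = 2: the last grid point may overshoot tN by floating-point epsilon
  vals <- stats::approx(signal$timestamps, signal$values, xout = tout,
                        rule = 2)$y
  sampled_signal(tout, vals, signal$axis, signal$quantity, target_rate)
}

#' Butterworth filter specification
#'
#' @param cutoff Cutoff frequency in Hz (the -3 dB point of a single pass).
#' @param order Filter order (>= 1); the pipeline default is 4th order.
#' @param kind `"lowpass"` or `"highpass"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff, order = 4L, kind = c("lowpass", "highpass")) {
  kind <- match.arg(kind)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (order < 1) stop("order must be >= 1", call. = FALSE)
  structure(list(cutoff = cutoff, order = as.integer(order), kind = kind),
            class = "filter_spec")
}

#' Apply a Butterworth filter
#'
#' Applies an IIR Butterworth filter to a uniformly sampled signal. By default
#' the filter is run forward and backward (zero phase: no lag, squared
#' magnitude response) so that filtered kinematic profiles can be compared
#' sample-by-sample across devices. Edge transients on short records are
#' suppressed by odd-reflection padding of up to three filter settling
#' lengths (`3 * fs / cutoff` samples) at each end.
#'
#' @param signal A uniformly sampled [sampled_signal].
#' @param spec A [filter_spec] (or cutoff in Hz, in which case `order`/`kind`
#'   apply).
#' @param zero_phase Apply forward-backward (default `TRUE`); `FALSE` gives a
#'   single causal pass with the textbook -3 dB point at the cutoff.
#' @param order,kind Used only when `spec` is a bare cutoff frequency.
#'
#' @return The filtered [sampled_signal] on the same time base.
#' @export
butterworth <- function(signal, spec, zero_phase = TRUE,
                        order = 4L, kind = c("lowpass", "highpass")) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!inherits(spec, "filter_spec")) {
    spec <- filter_spec(spec, order = order, kind = match.arg(kind))
  }
  assert_uniform(signal, "butterworth")
  n <- length(signal$values)
  if (n < 2) stop("filtering needs at least 2 samples", call. = FALSE)
  fs <- signal_rate(signal)
  if (spec$cutoff >= fs / 2) {
    stop(sprintf("cutoff %.3g Hz is not below the Nyquist frequency %.3g Hz",
                 spec$cutoff, fs / 2), call. = FALSE)
  }
  bf <- signal::butter(spec$order, 2 * spec$cutoff / fs,
                       type = if (spec$kind == "lowpass") "low" else "high")
  x <- signal$values
  # at least ~a hundred samples so the zero-state start-up transient of the
  # forward and backward passes dies inside the padding
  pad <- min(n - 1L, max(as.integer(ceiling(3 * fs / spec$cutoff)),
                         24L * (spec$order + 1L)))
  if (pad > 0) {
    left <- 2 * x[1] - x[(pad + 1):2]
    right <- 2 * x[n] - x[(n - 1):(n - pad)]
    xp <- c(left, x, right)
  } else {
    xp <- x
  }
  y <- as.numeric(signal::filter(bf, xp))
  if (isTRUE(zero_phase)) {
    y <- rev(as.numeric(signal::filter(bf, rev(y))))
  }
  y <- y[(pad + 1):(pad + n)]
  sampled_signal(signal$timestamps, y, signal$axis, signal$quantity,
                 signal$nominal_rate)
}

#' Cumulative trapezoid integration
#'
#' Integrates a uniformly sampled acceleration or velocity signal with zero
#' initial condition, demoting the quantity one level
#' (acceleration -> velocity -> displacement). Initial conditions are
#' absorbed by the downstream drift correction.
#'
#' @param signal A uniformly sampled [sampled_signal] whose quantity is
#'   `"acceleration"` or `"velocity"`.
#' @return The integrated [sampled_signal], starting at 0.
#' @export
cumulative_integrate <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (signal$quantity == "displacement") {
    stop("cannot integrate a displacement signal further", call. = FALSE)
  }
  assert_uniform(signal, "cumulative_integrate")
  if (length(signal$values) < 2) stop("integration needs at least 2 samples", call. = FALSE)
  y <- as.numeric(pracma::cumtrapz(signal$timestamps, signal$values))
  q <- if (signal$quantity == "acceleration") "velocity" else "displacement"
  sampled_signal(signal$timestamps, y, signal$axis, q, signal$nominal_rate)
}

#' Central-difference differentiation
#'
#' Differentiates a uniformly sampled signal with central differences
#' (one-sided at the ends), promoting the quantity one level
#' (displacement -> velocity -> acceleration).
#'
#' @param signal A uniformly sampled [sampled_signal] whose quantity is
#'   `"displacement"` or `"velocity"`.
#' @return The differentiated [sampled_signal].
#' @export
differentiate <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (signal$quantity == "acceleration") {
    stop("cannot differentiate an acceleration signal further", call. = FALSE)
  }
  assert_uniform(signal, "differentiate")
  n <- length(signal$values)
  if (n < 2) stop("differentiation needs at least 2 samples", call. = FALSE)
  dt <- (signal$timestamps[n] - signal$timestamps[1]) / (n - 1)
  y <- pracma::gradient(signal$values, dt)
  q <- if (signal$quantity == "displacement") "velocity" else "acceleration"
  sampled_signal(signal$timestamps, y, signal$axis, q, signal$nominal_rate)
}

#' Bundle displacement, velocity and acceleration on one time base
#'
#' @param displacement,velocity,acceleration [sampled_signal]s of the
#'   corresponding quantities sharing one identical uniform time base.
#' @return An object of class `kinematic_triplet`.
#' @export
kinematic_triplet <- function(displacement, velocity, acceleration) {
  stopifnot(inherits(displacement, "sampled_signal"),
            inherits(velocity, "sampled_signal"),
            inherits(acceleration, "sampled_signal"))
  if (displacement$quantity != "displacement" ||
      velocity$quantity != "velocity" ||
      acceleration$quantity != "acceleration") {
    stop("triplet components have the wrong quantities", call. = FALSE)
  }
  if (!isTRUE(all.equal(displacement$timestamps, velocity$timestamps)) ||
      !isTRUE(all.equal(displacement$timestamps, acceleration$timestamps))) {
    stop("triplet components must share one time base", call. = FALSE)
  }
  structure(list(displacement = displacement, velocity = velocity,
                 acceleration = acceleration),
            class = "kinematic_triplet")
}

#' @export
print.kinematic_triplet <- function(x, ...) {
  cat(sprintf("<kinematic_triplet> axis %s, %d samples over %.2f s\n",
              x$displacement$axis, length(x$displacement$values),
              diff(range(x$displacement$timestamps))))
  invisible(x)
}
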