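#' Double-integrate vertical acceleration to displacement
#'
#' Two cumulative trapezoid integrations with zero initial velocity and
#' displacement (trials begin seated and stationary). No drift correction is
#' applied here: a constant acceleration bias `b` grows into a `b t^2 / 2`
#' displacement error, which [highpass_drift_correct()] and
#' [zero_displacement_update()] exist to remove.
#'
#' @param accel A uniformly sampled VT [sampled_signal] of quantity
#'   `"acceleration"`.
#' @return The vertical displacement [sampled_signal].
#' @export
double_integrate_vt <- function(accel) {
  stopifnot(inherits(accel, "sampled_signal"))
  if (accel$quantity != "acceleration") {
    stop("double_integrate_vt expects an acceleration signal", call. = FALSE)
  }
  if (accel$axis != "VT") {
    stop("double_integrate_vt expects the VT axis", call. = FALSE)
  }
  cumulative_integrate(cumulative_integrate(accel))
}

#' High-pass drift correction
#'
#' Removes low-frequency integration drift with a zero-phase 4th-order
#' Butterworth high-pass at 0.1 Hz. On records much shorter than the filter
#' settling time the correction is unreliable, so a warning is raised below
#' 10 s.
#'
#' @param displacement A uniformly sampled displacement [sampled_signal].
#' @param cutoff High-pass cutoff in Hz (default 0.1).
#' @param order Filter order (default 4).
#' @return The drift-corrected displacement.
#' @export
highpass_drift_correct <- function(displacement, cutoff = 0.1, order = 4L) {
  stopifnot(inherits(displacement, "sampled_signal"))
  span <- diff(range(displacement$timestamps))
  if (span < 10) {
    warning(sprintf("record of %.1f s is short relative to the %.2g Hz high-pass settling time; drift correction may be unreliable",
                    span, cutoff), call. = FALSE)
  }
  butterworth(displacement, filter_spec(cutoff, order, "highpass"),
              zero_phase = TRUE)
}

#' Detect chair contacts in an STS-like vertical displacement
#'
#' Finds the instants at which the participant makes contact with the chair,
#' i.e. the displacement returns to its seated reference level. Candidate
#' seated regions are contiguous runs of samples below
#' `depth_frac` of the amplitude range above the global minimum, merged when
#' closer than `min_separation`; within each region the contact is refined by
#' the velocity sign — the first non-negative-velocity sample for a region
#' entered by a descent, or the last non-positive-velocity sample for the
#' region containing the trial start (the initial seated posture). This
#' refinement is exact on noiseless minimum-jerk profiles.
#'
#' @param displacement A uniformly sampled, drift-free (or detrended) VT
#'   displacement [sampled_signal].
#' @param min_separation Minimum time between contacts, s (default 1.0).
#' @param depth_frac Depth criterion as a fraction of the amplitude range
#'   (default 0.25).
#' @param include_start Treat the trial start as a seated contact.
#' @return A [contact_events] object, times on the sample grid.
#' @export
detect_chair_contacts <- function(displacement, min_separation = 1.0,
                                  depth_frac = 0.25, include_start = TRUE) {
  stopifnot(inherits(displacement, "sampled_signal"))
  assert_uniform(displacement, "detect_chair_contacts")
  x <- displacement$values
  t <- displacement$timestamps
  rng <- max(x) - min(x)
  if (rng < 1e-9) {
    stop("no displacement excursions: cannot detect chair contacts",
         call. = FALSE)
  }
  v <- differentiate(displacement)$values
  thr <- min(x) + depth_frac * rng
  mask <- x <= thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  if (nrow(runs) == 0) {
    stop("no displacement minima below the depth criterion", call. = FALSE)
  }
  # merge runs whose gap is shorter than min_separation
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- t[runs[i, 1]] - t[merged[nrow(merged), 2]]
      if (gap < min_separation) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  contacts <- numeric(0)
  for (i in seq_len(nrow(merged))) {
    idx <- merged[i, 1]:merged[i, 2]
    if (i == 1 && merged[1, 1] == 1L && include_start) {
      cand <- idx[v[idx] <= 0]
      ci <- if (length(cand)) max(cand) else idx[which.min(x[idx])]
    } else {
      cand <- idx[v[idx] >= 0]
      ci <- if (length(cand)) min(cand) else idx[which.min(x[idx])]
    }
    contacts <- c(contacts, t[ci])
  }
  if (!include_start && merged[1, 1] == 1L && nrow(merged) > 1 &&
      contacts[1] <= t[1] + 1e-9) {
    contacts <- contacts[-1]
  }
  contact_events(contacts, includes_start = include_start)
}

#' Zero-displacement update (ZDU) drift correction
#'
#' Subtracts a continuous piecewise-linear drift estimate that interpolates
#' the displacement values at the chair-contact instants, so the corrected
#' displacement is exactly zero at every contact. Before the first and after
#' the last contact the nearest segment's line is extrapolated. With a single
#' contact the correction degenerates to removing one constant offset (the
#' single-span mode used for TUG, where the correction is applied once over
#' the whole recording). A linear displacement drift between two contacts is
#' removed exactly; a constant-bias (quadratic) drift leaves at most
#' `b * gap^2 / 8` between contacts separated by `gap`.
#'
#' @param displacement A uniformly sampled displacement [sampled_signal].
#' @param contacts A [contact_events]; all times must lie within the signal's
#'   time span. Times are snapped to the nearest sample.
#' @return The corrected displacement, exactly 0 at every contact sample.
#' @export
zero_displacement_update <- function(displacement, contacts) {
  stopifnot(inherits(displacement, "sampled_signal"),
            inherits(contacts, "contact_events"))
  t <- displacement$timestamps
  x <- displacement$values
  tc <- contacts$contact_times
  if (any(tc < t[1] - 1e-9) || any(tc > t[length(t)] + 1e-9)) {
    stop("contact times outside the signal's time span", call. = FALSE)
  }
  idx <- vapply(tc, function(ti) which.min(abs(t - ti)), integer(1))
  idx <- unique(idx)
  if (length(idx) == 1) {
    drift <- rep(x[idx], length(t))
  } else {
    tcs <- t[idx]
    xcs <- x[idx]
    drift <- stats::approx(tcs, xcs, xout = t, rule = 2)$y
    k <- length(idx)
    s1 <- (xcs[2] - xcs[1]) / (tcs[2] - tcs[1])
    sk <- (xcs[k] - xcs[k - 1]) / (tcs[k] - tcs[k - 1])
    pre <- t < tcs[1]
    post <- t > tcs[k]
    drift[pre] <- xcs[1] + s1 * (t[pre] - tcs[1])
    drift[post] <- xcs[k] + sk * (t[post] - tcs[k])
  }
  y <- x - drift
  y[idx] <- 0  # exact at the anchors regardless of rounding
  sampled_signal(t, y, displacement$axis, "displacement",
                 displacement$nominal_rate)
}

#' Derive the full kinematic triplet from drift-corrected displacement
#'
#' Low-pass filters the displacement (zero-phase 4th-order Butterworth,
#' 5 Hz by default) and differentiates twice, so velocity is exactly the
#' numerical derivative of the filtered displacement and acceleration of the
#' velocity, all on one shared time base.
#'
#' @param displacement A uniformly sampled displacement [sampled_signal].
#' @param lowpass_cutoff Low-pass cutoff in Hz (default 5); `NULL` to skip
#'   filtering.
#' @return A `kinematic_triplet`.
#' @export
build_kinematics <- function(displacement, lowpass_cutoff = 5) {
  stopifnot(inherits(displacement, "sampled_signal"))
  assert_uniform(displacement, "build_kinematics")
  d <- if (is.null(lowpass_cutoff)) {
    displacement
  } else {
    butterworth(displacement, filter_spec(lowpass_cutoff, 4L, "lowpass"),
                zero_phase = TRUE)
  }
  v <- differentiate(d)
  a <- differentiate(v)
  kinematic_triplet(d, v, a)
}
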