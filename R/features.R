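#' Detect rise/descent phases from vertical kinematics
#'
#' Segments chair-rise and chair-descent movements with a sustained
#' velocity-threshold rule: a candidate rise is a run of vertical velocity
#' above `threshold_frac` of the peak absolute velocity sustained for at
#' least `min_phase` seconds (descents symmetric with negative velocity).
#' Onsets are refined backward to the last non-positive-velocity sample
#' before the run and offsets forward to the first non-positive sample after
#' it (sign-flipped for descents), which is exact on minimum-jerk profiles.
#' Candidates whose net displacement change is below a quarter of the
#' amplitude range are discarded, so vertical gait bounce during TUG walking
#' is not segmented as rise/descent cycles. Rises and descents are then
#' paired in temporal order.
#'
#' @param kin A `kinematic_triplet` of drift-corrected VT kinematics.
#' @param threshold_frac Velocity threshold as a fraction of the peak
#'   absolute velocity (default 0.1).
#' @param min_phase Minimum sustained duration of a phase, s (default 0.1).
#' @param min_excursion_frac Minimum displacement change across a phase as a
#'   fraction of the amplitude range (default 0.25).
#' @return A [phase_events] object.
#' @export
detect_phases <- function(kin, threshold_frac = 0.1, min_phase = 0.1,
                          min_excursion_frac = 0.25) {
  stopifnot(inherits(kin, "kinematic_triplet"))
  v <- kin$velocity$values
  d <- kin$displacement$values
  t <- kin$velocity$timestamps
  vmax <- max(abs(v))
  drange <- max(d) - min(d)
  if (vmax <= 0 || drange <= 1e-9) {
    stop("no movement detected in the vertical kinematics", call. = FALSE)
  }
  thr <- threshold_frac * vmax
  fs <- signal_rate(kin$velocity)
  min_len <- max(1L, as.integer(round(min_phase * fs)))

  find_events <- function(active, positive) {
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    runs <- cbind(starts, ends)[keep, , drop = FALSE]
    ev <- NULL
    for (i in seq_len(nrow(runs))) {
      j <- runs[i, 1]
      if (positive) while (j > 1 && v[j - 1] > 0) j <- j - 1L
      else while (j > 1 && v[j - 1] < 0) j <- j - 1L
      onset <- max(j - 1L, 1L)
      j <- runs[i, 2]
      n <- length(v)
      if (positive) while (j < n && v[j + 1] > 0) j <- j + 1L
      else while (j < n && v[j + 1] < 0) j <- j + 1L
      offset <- min(j + 1L, n)
      if (abs(d[offset] - d[onset]) >= min_excursion_frac * drange) {
        ev <- rbind(ev, c(onset, offset))
      }
    }
    ev
  }

  rises <- find_events(v > thr, TRUE)
  descents <- find_events(v < -thr, FALSE)
  if (is.null(rises) || is.null(descents)) {
    stop("no sustained rise/descent movement found", call. = FALSE)
  }
  # merge overlapping detections of the same movement (can arise when noise
  # splits one suprathreshold run), then pair each rise with the next descent
  dedupe <- function(ev) {
    ev <- ev[order(ev[, 1]), , drop = FALSE]
    out <- ev[1, , drop = FALSE]
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev[i, 1] <= out[nrow(out), 2]) {
        out[nrow(out), 2] <- max(out[nrow(out), 2], ev[i, 2])
      } else out <- rbind(out, ev[i, , drop = FALSE])
    }
    out
  }
  rises <- dedupe(rises)
  descents <- dedupe(descents)
  ro <- c(); rf <- c(); dn <- c(); df <- c()
  di <- 1L
  for (i in seq_len(nrow(rises))) {
    # the matching descent is the first one ending after this rise ends;
    # under noise its refined onset can overlap the rise offset by a sample,
    # so clamp rather than discard
    while (di <= nrow(descents) && descents[di, 2] <= rises[i, 2]) di <- di + 1L
    if (di > nrow(descents)) break
    ro <- c(ro, t[rises[i, 1]]); rf <- c(rf, t[rises[i, 2]])
    dn <- c(dn, max(t[descents[di, 1]], t[rises[i, 2]]))
    df <- c(df, t[descents[di, 2]])
    di <- di + 1L
  }
  if (length(ro) == 0) {
    stop("rises and descents could not be paired into cycles", call. = FALSE)
  }
  phase_events(ro, rf, dn, df)
}

new_feature_set <- function(task, total_time, mean_stand_time, mean_sit_time,
                            max_acceleration, max_velocity) {
  structure(list(task = task, total_time = total_time,
                 mean_stand_time = mean_stand_time,
                 mean_sit_time = mean_sit_time,
                 max_acceleration = max_acceleration,
                 max_velocity = max_velocity),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: total %.2f s", x$task, x$total_time))
  if (!is.na(x$mean_stand_time)) {
    cat(sprintf(", stand %.2f s, sit %.2f s", x$mean_stand_time,
                x$mean_sit_time))
  }
  cat(sprintf(", max vel %.2f m/s, max acc %.2f m/s^2\n", x$max_velocity,
              x$max_acceleration))
  invisible(x)
}

# peak values inside the task window [first rise onset, last descent offset]
window_peaks <- function(kin, t_from, t_to) {
  tt <- kin$velocity$timestamps
  sel <- tt >= t_from & tt <= t_to
  list(max_velocity = max(kin$velocity$values[sel]),
       max_acceleration = max(abs(kin$acceleration$values[sel])))
}

#' Sit-to-stand performance features
#'
#' Total time (initiation of the first rise to completion of the last
#' descent), mean standing-phase and sitting-phase movement durations, and
#' the peak upward velocity and peak absolute acceleration within the task
#' window. The sitting phase is the descent movement duration, treated
#' symmetrically with the standing (rise) phase.
#'
#' @param kin A VT `kinematic_triplet`.
#' @param phases A [phase_events] from [detect_phases()] (or simulator truth).
#' @return A `feature_set` with `task = "STS"`.
#' @export
sts_features <- function(kin, phases) {
  stopifnot(inherits(kin, "kinematic_triplet"), inherits(phases, "phase_events"))
  n <- n_cycles(phases)
  if (n < 1) stop("need at least one complete rise/descent cycle", call. = FALSE)
  t_from <- phases$rise_onsets[1]
  t_to <- phases$descent_offsets[n]
  pk <- window_peaks(kin, t_from, t_to)
  new_feature_set("STS",
                  total_time = t_to - t_from,
                  mean_stand_time = mean(phases$rise_offsets - phases$rise_onsets),
                  mean_sit_time = mean(phases$descent_offsets - phases$descent_onsets),
                  max_acceleration = pk$max_acceleration,
                  max_velocity = pk$max_velocity)
}

#' Timed-up-and-go performance features
#'
#' Total time (initiation of the chair rise to completion of the chair
#' descent) and the peak upward velocity and peak absolute acceleration over
#' that window. Exactly one rise/descent cycle is expected.
#'
#' @inheritParams sts_features
#' @return A `feature_set` with `task = "TUG"`.
#' @export
tug_features <- function(kin, phases) {
  stopifnot(inherits(kin, "kinematic_triplet"), inherits(phases, "phase_events"))
  n <- n_cycles(phases)
  if (n != 1) {
    stop(sprintf("TUG expects exactly one rise/descent cycle, found %d (rises at %s)",
                 n, paste(sprintf("%.2f", phases$rise_onsets), collapse = ", ")),
         call. = FALSE)
  }
  t_from <- phases$rise_onsets[1]
  t_to <- phases$descent_offsets[1]
  pk <- window_peaks(kin, t_from, t_to)
  new_feature_set("TUG",
                  total_time = t_to - t_from,
                  mean_stand_time = NA_real_, mean_sit_time = NA_real_,
                  max_acceleration = pk$max_acceleration,
                  max_velocity = pk$max_velocity)
}
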