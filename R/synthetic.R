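#' Simulation configuration for synthetic STS / TUG trials
#'
#' Defines the ground-truth motion geometry and the sensor models used to
#' render it. Defaults reproduce the clinical protocol geometry: five
#' sit-to-stand repetitions with a ~0.3 m vertical head excursion, and a TUG
#' consisting of a rise, a 3 m walk at ~1 m/s, a turn, the return walk and a
#' descent. Rise and descent transitions are minimum-jerk quintics
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, whose closed-form peak velocity
#' `1.875 * H / T` falls in the range observed for adults at the default
#' amplitude and durations.
#'
#' The inertial channel model is gravity-corrected acceleration at
#' `imu_rate` plus white Gaussian noise (`imu_noise_sd`) and a slowly varying
#' bias `b0 + b1 * t` — the minimal model producing the quadratic/cubic
#' displacement drift that the high-pass and ZDU corrections exist to
#' remove. The position channel model is displacement sampled near
#' `position_rate` with per-sample clock jitter (`position_jitter_sd`,
#' clamped to 45% of the sample interval so timestamps stay strictly
#' increasing) plus white measurement noise (`position_noise_sd`).
#'
#' @param task `"STS"` or `"TUG"`.
#' @param n_repetitions Number of STS cycles (default 5).
#' @param rise_amplitude Vertical head excursion per rise, m (default 0.30).
#' @param rise_duration,descent_duration Rise / descent movement durations, s.
#' @param stand_hold,sit_hold Dwell at the top / seated between STS cycles, s.
#'   Defaults are short (0.2 s) because the task is performed as quickly as
#'   possible.
#' @param lead_in,lead_out Quiet sitting before the first rise and after the
#'   last descent, s.
#' @param walk_distance,walk_speed TUG walk length (m) and speed (m/s).
#' @param step_frequency Stride rate, Hz; the vertical gait bounce runs at
#'   twice this (two vertical oscillations per stride).
#' @param bounce_amplitude Peak vertical gait oscillation during walking, m.
#' @param turn_duration Turn dwell between the outbound and return walks, s.
#' @param imu_rate,position_rate Sensor sampling rates, Hz.
#' @param position_jitter_sd Position-channel timestamp jitter SD, s.
#' @param imu_noise_sd IMU white-noise SD, m/s^2.
#' @param imu_bias_b0 Constant IMU bias, m/s^2.
#' @param imu_bias_slope_b1 Linear IMU bias slope, m/s^3.
#' @param position_noise_sd Position-channel white-noise SD, m.
#' @param seed Integer seed; identical configurations yield bit-identical
#'   trials.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(task = c("STS", "TUG"),
                              n_repetitions = 5L,
                              rise_amplitude = 0.30,
                              rise_duration = 0.6,
                              descent_duration = 1.0,
                              stand_hold = 0.2,
                              sit_hold = 0.2,
                              lead_in = 0.5,
                              lead_out = 0.5,
                              walk_distance = 3.0,
                              walk_speed = 1.0,
                              step_frequency = 2.0,
                              bounce_amplitude = 0.015,
                              turn_duration = 1.0,
                              imu_rate = 128,
                              position_rate = 30,
                              position_jitter_sd = 0.005,
                              imu_noise_sd = 0.02,
                              imu_bias_b0 = 0.005,
                              imu_bias_slope_b1 = 0.0005,
                              position_noise_sd = 0.005,
                              seed = 1L) {
  task <- match.arg(task)
  cfg <- list(task = task, n_repetitions = as.integer(n_repetitions),
              rise_amplitude = rise_amplitude, rise_duration = rise_duration,
              descent_duration = descent_duration, stand_hold = stand_hold,
              sit_hold = sit_hold, lead_in = lead_in, lead_out = lead_out,
              walk_distance = walk_distance, walk_speed = walk_speed,
              step_frequency = step_frequency,
              bounce_amplitude = bounce_amplitude,
              turn_duration = turn_duration,
              imu_rate = imu_rate, position_rate = position_rate,
              position_jitter_sd = position_jitter_sd,
              imu_noise_sd = imu_noise_sd, imu_bias_b0 = imu_bias_b0,
              imu_bias_slope_b1 = imu_bias_slope_b1,
              position_noise_sd = position_noise_sd,
              seed = as.integer(seed))
  strictly_pos <- c("rise_amplitude", "rise_duration", "descent_duration",
                    "walk_speed", "step_frequency", "imu_rate", "position_rate")
  for (nm in strictly_pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop(sprintf("%s must be > 0", nm), call. = FALSE)
    }
  }
  non_neg <- c("stand_hold", "sit_hold", "lead_in", "lead_out",
               "walk_distance", "turn_duration", "bounce_amplitude",
               "position_jitter_sd", "imu_noise_sd", "position_noise_sd")
  for (nm in non_neg) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop(sprintf("%s must be >= 0", nm), call. = FALSE)
    }
  }
  if (cfg$n_repetitions < 1) stop("n_repetitions must be >= 1", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# ---- piecewise-analytic motion model -------------------------------------
# A motion is a table of segments, each a hold, a minimum-jerk transition or
# a raised-cosine bounce about a constant level; displacement, velocity and
# acceleration are available in closed form everywhere.

mk_segment <- function(t0, dur, type, base, delta = 0, freq = 0, amp = 0) {
  data.frame(t0 = t0, t1 = t0 + dur, type = type, base = base,
             delta = delta, freq = freq, amp = amp,
             stringsAsFactors = FALSE)
}

build_motion <- function(segs) {
  segs <- segs[segs$t1 > segs$t0, , drop = FALSE]  # drop zero-duration pieces
  rownames(segs) <- NULL
  structure(list(segs = segs, t0 = segs$t0[1], t1 = segs$t1[nrow(segs)]),
            class = "motion_model")
}

motion_eval <- function(motion, t, deriv = 0L) {
  segs <- motion$segs
  tc <- pmin(pmax(t, motion$t0), motion$t1)
  idx <- findInterval(tc, segs$t0, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  out <- numeric(length(t))
  for (j in seq_len(nrow(segs))) {
    sel <- idx == j
    if (!any(sel)) next
    s <- segs[j, ]
    tl <- tc[sel] - s$t0
    Tt <- s$t1 - s$t0
    out[sel] <- switch(
      s$type,
      hold = if (deriv == 0L) rep(s$base, sum(sel)) else rep(0, sum(sel)),
      mj = {
        tau <- tl / Tt
        if (deriv == 0L) {
          s$base + s$delta * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
        } else if (deriv == 1L) {
          s$delta / Tt * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
        } else {
          s$delta / Tt^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
        }
      },
      bounce = {
        w <- 2 * pi * s$freq
        if (deriv == 0L) {
          s$base + s$amp / 2 * (1 - cos(w * tl))
        } else if (deriv == 1L) {
          s$amp / 2 * w * sin(w * tl)
        } else {
          s$amp / 2 * w^2 * cos(w * tl)
        }
      },
      stop("unknown segment type")
    )
  }
  # outside the span the motion holds its boundary value
  if (deriv > 0L) out[t < motion$t0 | t > motion$t1] <- 0
  out
}

# Evaluate a motion model on a uniform grid as a kinematic_triplet; the model
# itself travels along as an attribute so renderers can sample analytically.
motion_to_triplet <- function(motion, rate, axis) {
  k <- 0:floor((motion$t1 - motion$t0) * rate + 1e-9)
  t <- motion$t0 + k / rate
  tri <- kinematic_triplet(
    sampled_signal(t, motion_eval(motion, t, 0L), axis, "displacement", rate),
    sampled_signal(t, motion_eval(motion, t, 1L), axis, "velocity", rate),
    sampled_signal(t, motion_eval(motion, t, 2L), axis, "acceleration", rate)
  )
  attr(tri, "motion") <- motion
  tri
}

# ---- task generators ------------------------------------------------------

sts_vt_motion <- function(cfg) {
  segs <- mk_segment(0, cfg$lead_in, "hold", 0)
  t <- cfg$lead_in
  H <- cfg$rise_amplitude
  for (r in seq_len(cfg$n_repetitions)) {
    segs <- rbind(segs, mk_segment(t, cfg$rise_duration, "mj", 0, H))
    t <- t + cfg$rise_duration
    segs <- rbind(segs, mk_segment(t, cfg$stand_hold, "hold", H))
    t <- t + cfg$stand_hold
    segs <- rbind(segs, mk_segment(t, cfg$descent_duration, "mj", H, -H))
    t <- t + cfg$descent_duration
    segs <- rbind(segs, mk_segment(t, cfg$sit_hold, "hold", 0))
    t <- t + cfg$sit_hold
  }
  segs <- rbind(segs, mk_segment(t, cfg$lead_out, "hold", 0))
  build_motion(segs)
}

sts_true_events <- function(cfg) {
  cyc <- cfg$rise_duration + cfg$stand_hold + cfg$descent_duration + cfg$sit_hold
  ro <- cfg$lead_in + (seq_len(cfg$n_repetitions) - 1) * cyc
  rf <- ro + cfg$rise_duration
  dn <- rf + cfg$stand_hold
  df <- dn + cfg$descent_duration
  list(phases = phase_events(ro, rf, dn, df),
       contacts = contact_events(c(ro[1], df), includes_start = TRUE))
}

tug_motions <- function(cfg) {
  H <- cfg$rise_amplitude
  t_walk <- if (cfg$walk_distance > 0) cfg$walk_distance / cfg$walk_speed else 0
  # integer number of bounce cycles so walking starts and ends at zero
  # vertical velocity
  f_bounce <- 2 * cfg$step_frequency
  if (t_walk > 0) {
    n_cyc <- max(1, round(f_bounce * t_walk))
    f_bounce <- n_cyc / t_walk
  }
  t <- cfg$lead_in
  vt <- mk_segment(0, cfg$lead_in, "hold", 0)
  ap <- mk_segment(0, cfg$lead_in + cfg$rise_duration, "hold", 0)
  vt <- rbind(vt, mk_segment(t, cfg$rise_duration, "mj", 0, H))
  t <- t + cfg$rise_duration
  if (t_walk > 0) {
    vt <- rbind(vt, mk_segment(t, t_walk, "bounce", H, freq = f_bounce,
                               amp = cfg$bounce_amplitude))
    ap <- rbind(ap, mk_segment(t, t_walk, "mj", 0, cfg$walk_distance))
    t <- t + t_walk
  }
  vt <- rbind(vt, mk_segment(t, cfg$turn_duration, "hold", H))
  ap <- rbind(ap, mk_segment(t, cfg$turn_duration, "hold", cfg$walk_distance))
  t <- t + cfg$turn_duration
  if (t_walk > 0) {
    vt <- rbind(vt, mk_segment(t, t_walk, "bounce", H, freq = f_bounce,
                               amp = cfg$bounce_amplitude))
    ap <- rbind(ap, mk_segment(t, t_walk, "mj", cfg$walk_distance,
                               -cfg$walk_distance))
    t <- t + t_walk
  }
  vt <- rbind(vt, mk_segment(t, cfg$descent_duration, "mj", H, -H))
  ap <- rbind(ap, mk_segment(t, cfg$descent_duration + cfg$lead_out, "hold", 0))
  t <- t + cfg$descent_duration
  vt <- rbind(vt, mk_segment(t, cfg$lead_out, "hold", 0))
  list(VT = build_motion(vt), AP = build_motion(ap),
       rise_onset = cfg$lead_in,
       descent_offset = t)
}

#' Render the inertial (IMU) channel of a simulated trial
#'
#' Samples the ground-truth acceleration at `imu_rate` and adds white
#' Gaussian noise and the bias drift `b0 + b1 * t`. Gravity is assumed
#' already removed, matching the gravity-corrected acceleration the pipeline
#' takes as input. Seeded from `config$seed` (with a fixed per-channel,
#' per-axis offset) so the draw is reproducible independently of the
#' position channel.
#'
#' @param truth A `kinematic_triplet` produced by the simulator.
#' @param config A [simulation_config].
#' @return A [sampled_signal] of acceleration at `imu_rate`.
#' @export
render_imu <- function(truth, config) {
  stopifnot(inherits(truth, "kinematic_triplet"),
            inherits(config, "simulation_config"))
  motion <- attr(truth, "motion")
  t0 <- truth$acceleration$timestamps[1]
  tn <- truth$acceleration$timestamps[length(truth$acceleration$timestamps)]
  k <- 0:floor((tn - t0) * config$imu_rate + 1e-9)
  t <- t0 + k / config$imu_rate
  acc <- if (!is.null(motion)) {
    motion_eval(motion, t, 2L)
  } else {
    stats::approx(truth$acceleration$timestamps, truth$acceleration$values,
                  xout = t)$y
  }
  ax <- match(truth$acceleration$axis, c("VT", "AP", "ML")) - 1L
  set.seed(config$seed + 1L + 10L * ax)
  noise <- stats::rnorm(length(t), sd = config$imu_noise_sd)
  bias <- config$imu_bias_b0 + config$imu_bias_slope_b1 * (t - t0)
  sampled_signal(t, acc + noise + bias, truth$acceleration$axis,
                 "acceleration", config$imu_rate)
}

#' Render the position (headset) channel of a simulated trial
#'
#' Samples the ground-truth displacement near `position_rate` with per-sample
#' timestamp jitter (emulating the headset's dynamic clock) and additive
#' white measurement noise. Jitter is clamped to 45% of the nominal sample
#' interval, so consecutive timestamps remain strictly increasing with gaps
#' inside `1/rate * (1 +/- 0.9)`. Seeded from `config$seed` with a fixed
#' per-channel, per-axis offset.
#'
#' @inheritParams render_imu
#' @return A [sampled_signal] of displacement at a jittered ~`position_rate`.
#' @export
render_position <- function(truth, config) {
  stopifnot(inherits(truth, "kinematic_triplet"),
            inherits(config, "simulation_config"))
  motion <- attr(truth, "motion")
  t0 <- truth$displacement$timestamps[1]
  tn <- truth$displacement$timestamps[length(truth$displacement$timestamps)]
  dt <- 1 / config$position_rate
  k <- 0:floor((tn - t0) / dt + 1e-9)
  t_nom <- t0 + k * dt
  ax <- match(truth$displacement$axis, c("VT", "AP", "ML")) - 1L
  set.seed(config$seed + 2L + 10L * ax)
  jit <- stats::rnorm(length(t_nom), sd = config$position_jitter_sd)
  jit <- pmin(pmax(jit, -0.45 * dt), 0.45 * dt)
  t <- pmin(pmax(t_nom + jit, t0), tn)
  # clamping at the span edges may create ties at the very ends
  if (length(t) >= 2) {
    for (i in 2:length(t)) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + 1e-9
    t[t > tn] <- tn
    t <- unique(t)
  }
  d <- if (!is.null(motion)) {
    motion_eval(motion, t, 0L)
  } else {
    stats::approx(truth$displacement$timestamps, truth$displacement$values,
                  xout = t)$y
  }
  noise <- stats::rnorm(length(t), sd = config$position_noise_sd)
  sampled_signal(t, d + noise, truth$displacement$axis, "displacement",
                 config$position_rate)
}

new_simulated_trial <- function(task, config, truth, imu, position,
                                contacts, phases) {
  structure(list(task = task, config = config, truth = truth, imu = imu,
                 position = position, true_contacts = contacts,
                 true_phases = phases),
            class = "simulated_trial")
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf("<simulated_trial> %s, seed %d, %.1f s, axes: %s\n",
              x$task, x$config$seed,
              diff(range(x$truth$VT$displacement$timestamps)),
              paste(names(x$truth), collapse = ", ")))
  invisible(x)
}

#' Simulate a five-repetition sit-to-stand trial
#'
#' Generates the ground-truth vertical head trajectory (a concatenation of
#' minimum-jerk rises of amplitude `rise_amplitude` over `rise_duration`,
#' stand holds, minimum-jerk descents over `descent_duration` and seated
#' holds; displacement returns exactly to 0 at every chair contact) and
#' renders it through the IMU and position sensor models.
#'
#' @param config A [simulation_config] with `task = "STS"`.
#' @return A `simulated_trial` with elements `truth` (per-axis
#'   `kinematic_triplet`s on the dense internal grid), `imu` and `position`
#'   (per-axis [sampled_signal]s), `true_contacts`, `true_phases`, `config`.
#' @export
#' @examples
#' trial <- simulate_sts(simulation_config("STS", seed = 7))
#' trial$true_contacts
simulate_sts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$task != "STS") stop("config$task must be 'STS'", call. = FALSE)
  motion <- sts_vt_motion(config)
  truth_vt <- motion_to_triplet(motion, config$imu_rate, "VT")
  ev <- sts_true_events(config)
  new_simulated_trial(
    "STS", config,
    truth = list(VT = truth_vt),
    imu = list(VT = render_imu(truth_vt, config)),
    position = list(VT = render_position(truth_vt, config)),
    contacts = ev$contacts, phases = ev$phases
  )
}

#' Simulate a timed-up-and-go trial
#'
#' Ground truth: a minimum-jerk rise, an outbound walk whose
#' anterior-posterior (AP) displacement rises smoothly to `walk_distance`
#' with a raised-cosine vertical bounce at twice the step frequency, a turn
#' plateau, the return walk, and a minimum-jerk descent; net AP displacement
#' at the end is 0 and the maximum equals `walk_distance`.
#'
#' @param config A [simulation_config] with `task = "TUG"`.
#' @return A `simulated_trial` with VT and AP truth and channels.
#' @export
simulate_tug <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$task != "TUG") stop("config$task must be 'TUG'", call. = FALSE)
  m <- tug_motions(config)
  truth_vt <- motion_to_triplet(m$VT, config$imu_rate, "VT")
  truth_ap <- motion_to_triplet(m$AP, config$imu_rate, "AP")
  phases <- phase_events(m$rise_onset, m$rise_onset + config$rise_duration,
                         m$descent_offset - config$descent_duration,
                         m$descent_offset)
  contacts <- contact_events(c(m$rise_onset, m$descent_offset),
                             includes_start = TRUE)
  new_simulated_trial(
    "TUG", config,
    truth = list(VT = truth_vt, AP = truth_ap),
    imu = list(VT = render_imu(truth_vt, config),
               AP = render_imu(truth_ap, config)),
    position = list(VT = render_position(truth_vt, config),
                    AP = render_position(truth_ap, config)),
    contacts = contacts, phases = phases
  )
}

#' Simulate a trial of either task
#'
#' Dispatches on `config$task`.
#' @param config A [simulation_config].
#' @return A `simulated_trial`.
#' @export
simulate_trial <- function(config) {
  if (config$task == "STS") simulate_sts(config) else simulate_tug(config)
}
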