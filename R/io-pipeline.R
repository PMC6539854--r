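fmt_num <- function(x) sprintf("%.17g", x)

#' Write a single-channel CSV
#'
#' Two columns `time_s,value`, preceded by comment lines carrying the axis,
#' quantity, units and nominal rate. Values are printed with 17 significant
#' digits so a round trip is bit-exact.
#'
#' @param signal A [sampled_signal].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_channel_csv <- function(signal, path) {
  stopifnot(inherits(signal, "sampled_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axis=%s", signal$axis),
               sprintf("# quantity=%s", signal$quantity),
               sprintf("# units=%s", units_of(signal$quantity)),
               sprintf("# nominal_rate_hz=%s",
                       if (is.na(signal$nominal_rate)) "NA"
                       else fmt_num(signal$nominal_rate)),
               "time_s,value",
               paste(fmt_num(signal$timestamps), fmt_num(signal$values),
                     sep = ",")), con)
  invisible(path)
}

#' Read a single-channel CSV
#'
#' Parses the format written by [write_channel_csv()], validating
#' monotonicity and finiteness; malformed input raises an error naming the
#' file and data line.
#'
#' @param path File path.
#' @return A [sampled_signal].
#' @export
read_channel_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- grep("^#", lines, invert = TRUE)
  if (length(body) < 2 || !grepl("^time_s\\s*,\\s*value$", lines[body[1]])) {
    stop(sprintf("%s: malformed header (expected 'time_s,value')", path),
         call. = FALSE)
  }
  dat <- utils::read.csv(text = lines[body], header = TRUE)
  if (anyNA(dat$time_s) || anyNA(dat$value) ||
      any(!is.finite(dat$time_s)) || any(!is.finite(dat$value))) {
    bad <- which(!is.finite(dat$time_s) | !is.finite(dat$value))[1]
    stop(sprintf("%s: non-finite sample at data line %d", path, bad),
         call. = FALSE)
  }
  if (any(diff(dat$time_s) <= 0)) {
    bad <- which(diff(dat$time_s) <= 0)[1] + 1L
    stop(sprintf("%s: timestamps not strictly increasing at data line %d",
                 path, bad), call. = FALSE)
  }
  axis <- meta[["axis"]]; quantity <- meta[["quantity"]]
  if (is.null(axis) || is.null(quantity)) {
    stop(sprintf("%s: missing '# axis=' or '# quantity=' metadata", path),
         call. = FALSE)
  }
  rate <- meta[["nominal_rate_hz"]]
  rate <- if (is.null(rate) || identical(rate, "NA")) NA_real_ else as.numeric(rate)
  sampled_signal(dat$time_s, dat$value, axis, quantity, rate)
}

channel_file <- function(dir, stem, role, axis) {
  suffix <- if (axis == "VT") "" else paste0("_", tolower(axis))
  file.path(dir, sprintf("%s_%s%s.csv", stem, role, suffix))
}

#' Write a simulated trial to disk
#'
#' Emits per-channel CSVs (`<stem>_imu.csv`, `<stem>_pos.csv`, plus `_ap`
#' variants for TUG), a dense ground-truth kinematics CSV
#' (`<stem>_truth.csv`: `time_s,disp_m,vel_mps,acc_mps2`), and a JSON sidecar
#' `<stem>_meta.json` with the full configuration (including the seed) and
#' the true contact/phase times.
#'
#' @param trial A `simulated_trial`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem, default `"trial"`.
#' @return The meta-file path, invisibly.
#' @export
write_trial <- function(trial, dir, stem = "trial") {
  stopifnot(inherits(trial, "simulated_trial"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ax in names(trial$imu)) {
    write_channel_csv(trial$imu[[ax]], channel_file(dir, stem, "imu", ax))
  }
  for (ax in names(trial$position)) {
    write_channel_csv(trial$position[[ax]], channel_file(dir, stem, "pos", ax))
  }
  tr <- trial$truth$VT
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  con <- file(truth_path, "w")
  writeLines(c("# axis=VT", "time_s,disp_m,vel_mps,acc_mps2",
               paste(fmt_num(tr$displacement$timestamps),
                     fmt_num(tr$displacement$values),
                     fmt_num(tr$velocity$values),
                     fmt_num(tr$acceleration$values), sep = ",")), con)
  close(con)
  meta <- list(
    trial_id = stem, task = trial$task,
    config = unclass(trial$config),
    true_contacts = trial$true_contacts$contact_times,
    contacts_include_start = trial$true_contacts$includes_start,
    true_phases = unclass(trial$true_phases)
  )
  meta_path <- file.path(dir, paste0(stem, "_meta.json"))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(meta_path)
}

#' Read a trial recording from disk
#'
#' Reads the channel CSVs and JSON sidecar written by [write_trial()] into a
#' validated `trial_recording`: channels keyed by role and axis plus the
#' metadata (including true events for synthetic trials).
#'
#' @param dir Directory containing the files.
#' @param stem File-name stem.
#' @return An object of class `trial_recording` with elements `trial_id`,
#'   `task`, `channels` (named list of [sampled_signal]s, e.g. `imu_VT`,
#'   `pos_VT`) and `meta`.
#' @export
read_trial <- function(dir, stem = "trial") {
  meta_path <- file.path(dir, paste0(stem, "_meta.json"))
  if (!file.exists(meta_path)) {
    stop(sprintf("missing sidecar %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  channels <- list()
  for (role in c("imu", "pos")) {
    for (ax in c("VT", "AP", "ML")) {
      p <- channel_file(dir, stem, role, ax)
      if (file.exists(p)) {
        sig <- read_channel_csv(p)
        expected_q <- if (role == "imu") "acceleration" else "displacement"
        if (sig$quantity != expected_q) {
          stop(sprintf("%s: quantity '%s' does not match the %s role",
                       p, sig$quantity, role), call. = FALSE)
        }
        channels[[paste(role, ax, sep = "_")]] <- sig
      }
    }
  }
  if (is.null(channels$imu_VT) && is.null(channels$pos_VT)) {
    stop(sprintf("trial '%s': no VT channel found in %s", stem, dir),
         call. = FALSE)
  }
  structure(list(trial_id = meta$trial_id %||% stem,
                 task = meta$task, channels = channels, meta = meta),
            class = "trial_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-device analysis pipeline on one trial
#'
#' Executes the processing chain on the vertical channels of a trial:
#' resample both devices to the analysis rate and low-pass filter (zero-phase
#' 4th-order Butterworth, 5 Hz); double-integrate the inertial acceleration
#' to displacement and correct drift by the selected strategy; derive
#' displacement/velocity/acceleration triplets for both devices; time-align
#' them by cross-correlation of displacement; and compute per-quantity
#' agreement (NRMSE, zero-lag Xcor) plus mobility features per device.
#'
#' Drift strategies: `"zdu"` (default) detects chair contacts on a
#' high-pass-filtered copy of the integrated displacement (per-cycle for STS;
#' for TUG a single span anchored at the trial's seated start and end) and
#' subtracts the piecewise-linear ZDU estimate; `"hpf"` applies the 0.1 Hz
#' high-pass; `"hpf+zdu"` chains both; `"none"` leaves the raw integral.
#'
#' @param trial A `simulated_trial` or `trial_recording` with VT channels.
#' @param drift Drift-correction strategy (see above).
#' @param analysis_rate Common analysis rate, Hz (default 30).
#' @param lowpass_cutoff Low-pass cutoff, Hz (default 5).
#' @param max_lag Cross-correlation search half-width, s (default 2).
#' @param verbose Print one line per stage.
#' @return An object of class `pipeline_report`: `trial_id`, `task`,
#'   `drift`, `lag_s`, `nrmse_pct` and `xcor` (each with elements `D`, `V`,
#'   `A`), `contact_times_s`, and `features` (per device role), plus the
#'   intermediate `kinematics` for inspection.
#' @export
run_pipeline <- function(trial, drift = c("zdu", "hpf", "hpf+zdu", "none"),
                         analysis_rate = 30, lowpass_cutoff = 5, max_lag = 2,
                         verbose = FALSE) {
  drift <- match.arg(drift)
  say <- function(...) if (verbose) message(sprintf(...))
  if (inherits(trial, "simulated_trial")) {
    imu_vt <- trial$imu$VT; pos_vt <- trial$position$VT
    task <- trial$task; trial_id <- sprintf("sim-seed%d", trial$config$seed)
  } else if (inherits(trial, "trial_recording")) {
    imu_vt <- trial$channels$imu_VT; pos_vt <- trial$channels$pos_VT
    task <- trial$task; trial_id <- trial$trial_id
    if (is.null(imu_vt) || is.null(pos_vt)) {
      stop("pipeline requires both the imu_VT and pos_VT channels", call. = FALSE)
    }
  } else {
    stop("trial must be a simulated_trial or trial_recording", call. = FALSE)
  }

  say("[%s] resample both channels to %g Hz + %g Hz low-pass", trial_id,
      analysis_rate, lowpass_cutoff)
  lp <- filter_spec(lowpass_cutoff, 4L, "lowpass")
  pos_d <- butterworth(resample_uniform(pos_vt, analysis_rate), lp)
  imu_a <- butterworth(resample_uniform(imu_vt, analysis_rate), lp)

  say("[%s] double integration (%d samples)", trial_id, length(imu_a$values))
  disp_raw <- double_integrate_vt(imu_a)

  contacts <- NULL
  disp_corr <- disp_raw
  if (drift %in% c("hpf", "hpf+zdu")) {
    say("[%s] high-pass drift correction", trial_id)
    disp_corr <- suppressWarnings(highpass_drift_correct(disp_corr))
  }
  if (drift %in% c("zdu", "hpf+zdu")) {
    if (identical(task, "TUG")) {
      tt <- disp_corr$timestamps
      contacts <- contact_events(c(tt[1], tt[length(tt)]),
                                 includes_start = TRUE)
      say("[%s] single-span ZDU over the whole recording", trial_id)
    } else {
      # detect on a high-passed copy (the raw integral drifts by metres, which
      # swamps the range-based minima criterion); the correction itself is
      # applied to disp_corr
      detect_on <- if (drift == "zdu") {
        suppressWarnings(highpass_drift_correct(disp_corr))
      } else {
        disp_corr
      }
      contacts <- detect_chair_contacts(detect_on)
      say("[%s] ZDU at %d detected contacts", trial_id,
          length(contacts$contact_times))
    }
    disp_corr <- zero_displacement_update(disp_corr, contacts)
  }

  say("[%s] derive kinematic triplets", trial_id)
  kin_imu <- build_kinematics(disp_corr, lowpass_cutoff)
  kin_pos <- build_kinematics(pos_d, lowpass_cutoff)

  say("[%s] cross-correlation alignment", trial_id)
  lag <- estimate_lag(kin_imu$displacement, kin_pos$displacement, max_lag)
  agree <- lapply(c(D = "displacement", V = "velocity", A = "acceleration"),
                  function(q) agreement(kin_imu[[q]], kin_pos[[q]], lag))

  say("[%s] mobility features", trial_id)
  feat_of <- function(kin) {
    tryCatch({
      ph <- detect_phases(kin)
      if (identical(task, "TUG")) tug_features(kin, ph)
      else sts_features(kin, ph)
    }, error = function(e) {
      warning(sprintf("[%s] feature extraction failed: %s", trial_id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  features <- list(position = feat_of(kin_pos), imu = feat_of(kin_imu))

  structure(list(
    trial_id = trial_id, task = task, drift = drift,
    lag_s = lag,
    nrmse_pct = lapply(agree, `[[`, "nrmse_pct"),
    xcor = lapply(agree, `[[`, "xcor"),
    n_samples = agree$D$n_samples,
    contact_times_s = if (!is.null(contacts)) contacts$contact_times,
    features = features,
    kinematics = list(imu = kin_imu, position = kin_pos)
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %s (%s, drift=%s)\n", x$trial_id, x$task,
              x$drift))
  cat(sprintf("  lag %.3f s over %d samples\n", x$lag_s, x$n_samples))
  cat(sprintf("  NRMSE%%  D %.2f  V %.2f  A %.2f\n",
              x$nrmse_pct$D, x$nrmse_pct$V, x$nrmse_pct$A))
  cat(sprintf("  Xcor    D %.3f  V %.3f  A %.3f\n",
              x$xcor$D, x$xcor$V, x$xcor$A))
  if (!is.null(x$features$position)) {
    cat("  features (position): "); print(x$features$position)
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Drops the bulky intermediate kinematics and writes the scalar results
#' (lag, per-quantity NRMSE/Xcor, contact times, features) as JSON.
#'
#' @param report A `pipeline_report`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- report[c("trial_id", "task", "drift", "lag_s", "nrmse_pct", "xcor",
                  "n_samples", "contact_times_s")]
  out$features <- lapply(report$features, function(f) {
    if (is.null(f)) NULL else {
      list(task = f$task, total_time_s = f$total_time,
           mean_stand_time_s = f$mean_stand_time,
           mean_sit_time_s = f$mean_sit_time,
           max_acceleration_mps2 = f$max_acceleration,
           max_velocity_mps = f$max_velocity)
    }
  })
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Write derived kinematics to CSV
#'
#' Columns `time_s,disp_m,vel_mps,acc_mps2`, the exchange format for the
#' agreement and feature stages.
#'
#' @param kin A `kinematic_triplet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kinematics_csv <- function(kin, path) {
  stopifnot(inherits(kin, "kinematic_triplet"))
  con <- file(path, "w")
  writeLines(c(sprintf("# axis=%s", kin$displacement$axis),
               "time_s,disp_m,vel_mps,acc_mps2",
               paste(fmt_num(kin$displacement$timestamps),
                     fmt_num(kin$displacement$values),
                     fmt_num(kin$velocity$values),
                     fmt_num(kin$acceleration$values), sep = ",")), con)
  close(con)
  invisible(path)
}

#' Read kinematics written by [write_kinematics_csv()]
#'
#' @param path File path.
#' @return A `kinematic_triplet`.
#' @export
read_kinematics_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  axis <- sub(".*axis=", "", meta[grepl("axis=", meta)][1])
  if (is.na(axis) || !axis %in% c("VT", "AP", "ML")) axis <- "VT"
  dat <- utils::read.csv(text = grep("^#", lines, invert = TRUE, value = TRUE))
  if (any(diff(dat$time_s) <= 0)) {
    stop(sprintf("%s: timestamps not strictly increasing", path), call. = FALSE)
  }
  kinematic_triplet(
    sampled_signal(dat$time_s, dat$disp_m, axis, "displacement"),
    sampled_signal(dat$time_s, dat$vel_mps, axis, "velocity"),
    sampled_signal(dat$time_s, dat$acc_mps2, axis, "acceleration")
  )
}
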