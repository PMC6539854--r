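test_that("double integration reproduces closed forms", {
  t <- uniform_grid(30, 12)
  zero <- sampled_signal(t, rep(0, length(t)), "VT", "acceleration", 30)
  expect_true(all(double_integrate_vt(zero)$values == 0))

  bias <- sampled_signal(t, rep(0.05, length(t)), "VT", "acceleration", 30)
  d <- double_integrate_vt(bias)
  expect_equal(d$values[length(t)], 0.5 * 0.05 * 12^2, tolerance = 1e-6)

  v <- sampled_signal(t, t, "VT", "velocity", 30)
  expect_error(double_integrate_vt(v), "acceleration")
  ap <- sampled_signal(t, rep(1, length(t)), "AP", "acceleration", 30)
  expect_error(double_integrate_vt(ap), "VT")
})

test_that("high-pass drift correction removes a ramp but passes a 1 Hz sine", {
  t <- uniform_grid(30, 60)
  ramp <- sampled_signal(t, 0.01 * t, "VT", "displacement", 30)
  out <- highpass_drift_correct(ramp)
  expect_lt(max(abs(out$values)), 0.1 * 0.01 * 60)

  zero <- sampled_signal(t, rep(0, length(t)), "VT", "displacement", 30)
  expect_true(all(abs(highpass_drift_correct(zero)$values) < 1e-12))

  s <- sine_signal(1, 30, 60)
  out <- highpass_drift_correct(s)
  mid <- t > 20 & t < 40
  ratio <- fit_amplitude(t[mid], out$values[mid], 1)
  expect_gt(ratio, 0.99)
  expect_lt(ratio, 1.001)
})

test_that("short records trigger the reliability warning", {
  s <- sine_signal(1, 30, 8)
  expect_warning(highpass_drift_correct(s), "unreliable")
})

test_that("contacts are recovered on a noiseless simulated STS trial", {
  tr <- simulate_sts(noiseless_config("STS"))
  disp <- resample_uniform(tr$position$VT, 30)
  ct <- detect_chair_contacts(disp)
  expect_equal(length(ct$contact_times), 6L)
  expect_lt(max(abs(ct$contact_times - tr$true_contacts$contact_times)), 0.1)
})

test_that("contact detection rejects signals without excursions", {
  t <- uniform_grid(30, 10)
  flat <- sampled_signal(t, rep(1, length(t)), "VT", "displacement", 30)
  expect_error(detect_chair_contacts(flat), "excursion")
})

test_that("contacts survive position-channel noise at the default level", {
  errs <- vapply(1:10, function(s) {
    tr <- simulate_sts(simulation_config("STS", seed = s))
    disp <- butterworth(resample_uniform(tr$position$VT, 30),
                        filter_spec(5, 4, "lowpass"))
    ct <- detect_chair_contacts(disp)
    expect_equal(length(ct$contact_times), 6L)
    max(abs(ct$contact_times - tr$true_contacts$contact_times))
  }, numeric(1))
  # velocity-sign refinement wanders a few samples in the slow minimum-jerk
  # tails once noise exceeds the local velocity
  expect_lt(median(errs), 0.2)
  expect_lt(max(errs), 0.35)
})

test_that("ZDU is a no-op when displacement is already zero at contacts", {
  tr <- simulate_sts(noiseless_config("STS"))
  disp <- resample_uniform(tr$truth$VT$displacement, 30)
  out <- zero_displacement_update(disp, tr$true_contacts)
  # the 30 Hz grid interpolates the minimum-jerk tail to ~5e-8 at a contact
  # sample, so the drift estimate is that small rather than exactly zero
  expect_lt(max(abs(out$values - disp$values)), 1e-6)
})

test_that("ZDU removes a linear drift exactly and bounds a quadratic one", {
  tr <- simulate_sts(noiseless_config("STS"))
  disp <- resample_uniform(tr$truth$VT$displacement, 30)
  t <- disp$timestamps

  lin <- sampled_signal(t, disp$values + 0.01 * t, "VT", "displacement", 30)
  out <- zero_displacement_update(lin, tr$true_contacts)
  expect_lt(max(abs(out$values - disp$values)), 1e-6)

  # parabola vs its chord deviates by at most b * gap^2 / 8 between contacts
  # (outside the contacted span the nearest chord is extrapolated, so the
  # bound applies to the interior)
  quad <- sampled_signal(t, disp$values + 0.5 * 0.05 * t^2, "VT",
                         "displacement", 30)
  out <- zero_displacement_update(quad, tr$true_contacts)
  ctimes <- tr$true_contacts$contact_times
  gap <- max(diff(ctimes))
  interior <- t >= min(ctimes) & t <= max(ctimes)
  expect_lt(max(abs(out$values[interior] - disp$values[interior])),
            0.05 * gap^2 / 8 + 1e-6)
})

test_that("ZDU rejects contacts outside the record", {
  t <- uniform_grid(30, 5)
  disp <- sampled_signal(t, sin(t), "VT", "displacement", 30)
  expect_error(zero_displacement_update(disp, contact_events(c(1, 9))),
               "time span")
})

test_that("corrected displacement is exactly zero at every contact sample", {
  tr <- simulate_sts(simulation_config("STS", seed = 6))
  lp <- butterworth(resample_uniform(tr$imu$VT, 30), filter_spec(5, 4, "lowpass"))
  raw <- double_integrate_vt(lp)
  ct <- detect_chair_contacts(suppressWarnings(highpass_drift_correct(raw)))
  out <- zero_displacement_update(raw, ct)
  idx <- vapply(ct$contact_times,
                function(ti) which.min(abs(out$timestamps - ti)), integer(1))
  expect_true(all(abs(out$values[idx]) < 1e-9))
})

test_that("ZDU reduces displacement error whenever an IMU bias is present", {
  for (b0 in c(0.01, 0.05)) {
    cfg <- noiseless_config("STS")
    cfg$imu_bias_b0 <- b0
    tr <- simulate_sts(cfg)
    lp <- butterworth(resample_uniform(tr$imu$VT, 30),
                      filter_spec(5, 4, "lowpass"))
    raw <- double_integrate_vt(lp)
    truth <- resample_uniform(tr$truth$VT$displacement, 30)
    n <- min(length(raw$values), length(truth$values))
    out <- zero_displacement_update(raw, tr$true_contacts)
    rmse <- function(x) sqrt(mean((x[1:n] - truth$values[1:n])^2))
    expect_lt(rmse(out$values), rmse(raw$values))
  }
})

test_that("build_kinematics recovers truth velocity to central-difference accuracy", {
  tr <- simulate_sts(noiseless_config("STS"))
  kin <- build_kinematics(resample_uniform(tr$truth$VT$displacement, 30))
  v_true <- resample_uniform(tr$truth$VT$velocity, 30)
  n <- min(length(kin$velocity$values), length(v_true$values))
  peak <- max(abs(v_true$values))
  # pointwise truncation error dt^2/6 * max|jerk| is ~1.6% of the peak at
  # 30 Hz (largest at the jerk extremes, not at the velocity peak itself)
  expect_lt(max(abs(kin$velocity$values[1:n] - v_true$values[1:n])),
            0.025 * peak)
  expect_equal(max(kin$velocity$values), peak, tolerance = 0.02)
})

test_that("build_kinematics yields an exactly self-consistent triplet", {
  tr <- simulate_sts(noiseless_config("STS"))
  kin <- build_kinematics(resample_uniform(tr$truth$VT$displacement, 30))
  expect_identical(kin$velocity$values, differentiate(kin$displacement)$values)
  expect_identical(kin$acceleration$values, differentiate(kin$velocity)$values)
  flat <- sampled_signal(uniform_grid(30, 10), rep(3, 301), "VT",
                         "displacement", 30)
  kin <- build_kinematics(flat)
  expect_lt(max(abs(kin$velocity$values)), 1e-9)
  expect_lt(max(abs(kin$acceleration$values)), 1e-7)
})
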