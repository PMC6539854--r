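# shared fixtures: all inputs are generated in code

uniform_grid <- function(rate, duration, t0 = 0) t0 + seq(0, duration, by = 1 / rate)

sine_signal <- function(freq, rate, duration, amplitude = 1,
                        quantity = "displacement", axis = "VT") {
  t <- uniform_grid(rate, duration)
  sampled_signal(t, amplitude * sin(2 * pi * freq * t), axis, quantity, rate)
}

# least-squares amplitude of a sinusoid of known frequency (steady-state
# magnitude estimator for filter-response tests)
fit_amplitude <- function(t, y, freq) {
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  beta <- qr.coef(qr(X), y)
  sqrt(sum(beta^2))
}

# configuration with every noise and drift source switched off
noiseless_config <- function(task = "STS", ...) {
  simulation_config(task, imu_noise_sd = 0, imu_bias_b0 = 0,
                    imu_bias_slope_b1 = 0, position_noise_sd = 0,
                    position_jitter_sd = 0, ...)
}

# the position-device processing path: resample to the analysis rate and
# derive kinematics
position_kinematics <- function(trial, rate = 30) {
  build_kinematics(butterworth(resample_uniform(trial$position$VT, rate),
                               filter_spec(5, 4, "lowpass")))
}

# construction-arithmetic ground truth for STS trials
sts_truth_times <- function(cfg) {
  cyc <- cfg$rise_duration + cfg$stand_hold + cfg$descent_duration + cfg$sit_hold
  total <- (cfg$n_repetitions - 1) * cyc + cfg$rise_duration +
    cfg$stand_hold + cfg$descent_duration
  list(total = total, cycle = cyc)
}
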