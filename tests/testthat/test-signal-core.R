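test_that("sampled_signal enforces its invariants", {
  expect_error(sampled_signal(c(0, 1, 1), c(1, 2, 3), "VT", "displacement"),
               "strictly increasing")
  expect_error(sampled_signal(c(0, 1), c(1, 2, 3), "VT", "displacement"),
               "same length")
  expect_error(sampled_signal(c(0, 1), c(1, NA), "VT", "displacement"), "NA")
})

test_that("resampling maps jittered input onto the exact uniform grid", {
  set.seed(1)
  t <- seq(0, 12, by = 1 / 30) + runif(361, -0.005, 0.005)
  t <- sort(t)
  const <- sampled_signal(t, rep(2, length(t)), "VT", "displacement", 30)
  out <- resample_uniform(const, 30)
  expect_equal(diff(out$timestamps), rep(1 / 30, length(out$timestamps) - 1),
               tolerance = 1e-12)
  expect_true(all(abs(out$values - 2) < 1e-12))

  # downsampled sine matches the analytic sine at the output grid times
  s <- sine_signal(1, 128, 10)
  out <- resample_uniform(s, 30)
  expect_lt(max(abs(out$values - sin(2 * pi * out$timestamps))), 1e-3)
})

test_that("resampling a signal already on the target grid returns it unchanged", {
  s <- sine_signal(1, 30, 10)
  out <- resample_uniform(s, 30)
  expect_equal(length(out$values), length(s$values))
  expect_lt(max(abs(out$values - s$values)), 1e-12)
})

test_that("upsampling past twice the input rate warns about aliasing", {
  s <- sine_signal(1, 30, 5)
  expect_warning(resample_uniform(s, 100), "aliasing")
})

test_that("low-pass DC gain is one and the cutoff sits at -3 dB", {
  t <- uniform_grid(128, 5)
  const <- sampled_signal(t, rep(1, length(t)), "VT", "acceleration", 128)
  out <- butterworth(const, filter_spec(5, 4, "lowpass"))
  mid <- seq(100, length(t) - 100)
  expect_lt(max(abs(out$values[mid] - 1)), 1e-9)

  s <- sine_signal(5, 128, 30)
  single <- butterworth(s, filter_spec(5, 4, "lowpass"), zero_phase = FALSE)
  mid <- s$timestamps > 10 & s$timestamps < 25
  amp <- fit_amplitude(s$timestamps[mid], single$values[mid], 5)
  expect_equal(amp, 1 / sqrt(2), tolerance = 0.02)
})

test_that("single-pass gains follow the analytic Butterworth magnitude", {
  # |H(f)| = (1 + (f/fc)^(2n))^(-1/2) for the low-pass; (fc/f) for high-pass.
  # Sampled fast relative to f so bilinear-transform warping is negligible.
  s <- sine_signal(10, 1024, 30)
  out <- butterworth(s, filter_spec(5, 4, "lowpass"), zero_phase = FALSE)
  mid <- s$timestamps > 10 & s$timestamps < 25
  expect_equal(fit_amplitude(s$timestamps[mid], out$values[mid], 10),
               (1 + (10 / 5)^8)^(-1 / 2), tolerance = 0.02)

  s <- sine_signal(0.02, 30, 600)
  out <- butterworth(s, filter_spec(0.1, 4, "highpass"), zero_phase = FALSE)
  mid <- s$timestamps > 200 & s$timestamps < 500
  expect_equal(fit_amplitude(s$timestamps[mid], out$values[mid], 0.02),
               (1 + (0.1 / 0.02)^8)^(-1 / 2), tolerance = 0.02)
})

test_that("filtering rejects non-uniform sampling", {
  s <- sampled_signal(c(0, 0.1, 0.3, 0.35, 0.6), rnorm(5), "VT", "displacement")
  expect_error(butterworth(s, filter_spec(1, 4, "lowpass")), "uniform")
})

test_that("trapezoid integration matches closed forms and demotes quantity", {
  t <- uniform_grid(100, 1)
  a <- sampled_signal(t, rep(1, length(t)), "VT", "acceleration", 100)
  v <- cumulative_integrate(a)
  expect_equal(v$quantity, "velocity")
  expect_equal(v$values, t, tolerance = 1e-12)

  # a(t) = -(2pi)^2 * 0.1 * sin(2pi t), zero initial conditions:
  # v(t) = 0.1*2pi*(cos(2pi t) - 1), d(t) = 0.1*sin(2pi t) - 0.1*2pi*t
  a <- sampled_signal(t, -(2 * pi)^2 * 0.1 * sin(2 * pi * t), "VT",
                      "acceleration", 100)
  d <- cumulative_integrate(cumulative_integrate(a))
  expect_equal(d$quantity, "displacement")
  expect_lt(max(abs(d$values - (0.1 * sin(2 * pi * t) - 0.1 * 2 * pi * t))),
            1e-3)

  z <- sampled_signal(t, rep(0, length(t)), "VT", "acceleration", 100)
  expect_true(all(cumulative_integrate(z)$values == 0))
  dd <- sampled_signal(t, t, "VT", "displacement", 100)
  expect_error(cumulative_integrate(dd), "displacement")
})

test_that("central differences match analytic derivatives and promote quantity", {
  t <- uniform_grid(100, 2)
  ramp <- sampled_signal(t, 0.5 * t, "VT", "displacement", 100)
  v <- differentiate(ramp)
  expect_equal(v$quantity, "velocity")
  expect_lt(max(abs(v$values - 0.5)), 1e-10)

  s <- sine_signal(1, 100, 2)
  v <- differentiate(s)
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(v$values[interior] - 2 * pi * cos(2 * pi * t[interior]))),
            1e-2)

  acc <- sampled_signal(t, t, "VT", "acceleration", 100)
  expect_error(differentiate(acc), "acceleration")
})

test_that("integrate-then-differentiate round trip reproduces smooth input", {
  t <- uniform_grid(128, 30)
  x <- sampled_signal(t, sin(2 * pi * 0.03 * t), "VT", "velocity", 128)
  back <- differentiate(cumulative_integrate(x))
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(back$values[interior] - x$values[interior])), 1e-6)
})

test_that("resampling, filtering, integration and differentiation are linear", {
  set.seed(7)
  t <- uniform_grid(64, 4)
  x <- sampled_signal(t, rnorm(length(t)), "VT", "velocity", 64)
  y <- sampled_signal(t, rnorm(length(t)), "VT", "velocity", 64)
  comb <- sampled_signal(t, 2.5 * x$values - 1.3 * y$values, "VT", "velocity", 64)
  for (op in list(function(s) resample_uniform(s, 32),
                  function(s) butterworth(s, filter_spec(5, 4, "lowpass")),
                  cumulative_integrate,
                  differentiate)) {
    lhs <- op(comb)$values
    rhs <- 2.5 * op(x)$values - 1.3 * op(y)$values
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("kinematic_triplet rejects mismatched time bases and quantities", {
  t <- uniform_grid(30, 2)
  d <- sampled_signal(t, sin(t), "VT", "displacement", 30)
  v <- sampled_signal(t, cos(t), "VT", "velocity", 30)
  a <- sampled_signal(t + 0.01, -sin(t), "VT", "acceleration", 30)
  expect_error(kinematic_triplet(d, v, a), "time base")
  expect_error(kinematic_triplet(d, d, d), "quantities")
})
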