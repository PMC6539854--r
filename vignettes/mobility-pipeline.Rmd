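---
title: "From raw sensor channels to mobility features: the mobsense pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw sensor channels to mobility features: the mobsense pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobsense)
```

## The measurement problem

Instrumented sit-to-stand (STS) and timed-up-and-go (TUG) tests produce two
very different vertical signals for the same movement: a head-worn device
reports fused 3-D *position* at a jittered ~30 Hz, while body-worn inertial
units report gravity-corrected *acceleration* at a clean 128 Hz. To compare
the devices — and to extract clinically meaningful timings from either —
both must be brought onto one uniform time base, the acceleration must be
double-integrated to displacement without drowning in drift, and the
resulting kinematic profiles must be aligned and scored. `mobsense`
implements that chain end to end, plus a simulator that generates trials
with known ground truth so each stage can be validated quantitatively.

## Signal model and processing chain

Every channel is a `sampled_signal`: strictly increasing timestamps, one
scalar value per sample, a body axis (VT/AP/ML) and a physical quantity.
The pipeline (`run_pipeline()`) executes:

1. **Resampling** to 30 Hz by linear interpolation onto the grid anchored at
   the first timestamp. Linear interpolation is robust to the headset's
   jittered clock and introduces no ringing; the anchor choice is arbitrary
   and any consistent choice would do.
2. **Low-pass filtering**, zero-phase 4th-order Butterworth at 5 Hz.
   Zero-phase (forward-backward) is the default everywhere because profiles
   are later compared sample-by-sample: a causal pass would add a
   frequency-dependent lag that corrupts NRMSE even between perfectly
   agreeing devices. A `zero_phase = FALSE` flag exposes the single-pass
   response, whose -3 dB point sits at the cutoff.
3. **Double integration** of VT acceleration with the trapezoid rule and
   zero initial conditions (trials begin seated and stationary; any residual
   initial-condition error is absorbed by the drift correction).
4. **Drift correction**, either a 0.1 Hz 4th-order high-pass, a
   zero-displacement update (ZDU), or both (`drift = "hpf"`, `"zdu"`,
   `"hpf+zdu"`). They are alternatives rather than one fixed sequence
   because the appropriate choice depends on how many chair contacts a task
   offers; the default is ZDU, per-cycle for STS and single-span for TUG.
5. **Kinematic triplets** by successive central differences of the filtered
   displacement, so velocity is exactly the numerical derivative of the
   stored displacement, and acceleration of the velocity.
6. **Alignment and agreement**: integer-sample lag maximizing the
   normalized cross-correlation (coefficient form, so amplitude offsets and
   scalings cannot bias the lag), then NRMSE and zero-lag Pearson
   correlation per quantity.
7. **Features**: task duration, phase durations, and peak velocity /
   acceleration from the velocity-threshold segmentation described below.

## The zero-displacement update

Between chair contacts the participant's height is unconstrained, but *at*
a contact it returns to the seated reference. ZDU therefore subtracts the
continuous piecewise-linear function interpolating the integrated
displacement at the contact instants; before the first and after the last
contact the nearest segment's line is extrapolated. A piecewise-*linear*
correction (rather than a per-cycle step offset) is continuous, so it adds
no spurious velocity spikes on differentiation; it removes a linear drift
between contacts exactly, and leaves at most `b·Δ²/8` of a constant-bias
drift `b` between contacts `Δ` apart. With the STS default geometry
(`Δ ≈ 2 s`) even the deliberately harsh bias of 0.05 m/s² used in the
stress tests leaves only ~2.5 cm against a 30 cm movement; a single-span
correction over a ~10 s TUG leaves `b·10²/8`, which is why TUG displacement
agreement is structurally worse than STS — the pattern the acceptance
suite checks.

**Contact detection** is the one genuinely unspecified ingredient, and the
package's rule is: candidate seated regions are contiguous runs of samples
below 25% of the amplitude range above the global minimum, merged when
closer than 1 s; within a region the contact is the first
non-negative-velocity sample (a descent just ended), or, for the region
containing the trial start, the last non-positive-velocity sample (a rise
is about to begin). On noiseless minimum-jerk profiles this is exact to one
sample. Detection runs on a *high-pass-filtered copy* of the integrated
displacement: the raw integral can drift by metres, which swamps a
range-based criterion, while the 0.1 Hz high-pass leaves millimetre-scale
residuals. (A cubic-polynomial detrend was tried instead and rejected: it
cannot follow the random-walk component of integrated noise and misdetected
contacts an order of magnitude more often.) The correction itself is always
applied to the uncorrected integral.

## Phase segmentation and features

A rise is a run of vertical velocity above 10% of the trial's peak absolute
velocity sustained for at least 0.1 s, refined backward to the last
non-positive-velocity sample (the movement onset) and forward to the first
one after (the movement end); descents are symmetric with negative
velocity. Two guards make the rule robust:

- a candidate phase must change displacement by at least 25% of the range —
  this rejects the walking bounce during TUG, whose peak vertical velocity
  (~0.19 m/s at the default 1.5 cm bounce) exceeds the 10% threshold but
  whose net excursion is centimetres;
- a rise is paired with the first descent *ending* after it, clamping a
  one-sample onset/offset overlap, because under noise the refined
  boundaries of adjacent phases can touch.

The "sitting phase" is the descent movement duration (onset to offset of
the downward movement), treated symmetrically with the standing (rise)
phase; seated dwell between cycles is not part of either. Peak velocity is
the maximum *upward* velocity inside the task window, matching the
convention that sub-1 m/s chair-rise peaks, not descent minima, are
reported. The task duration runs from the first rise onset to the last
descent offset, which makes it invariant to quiet sitting appended at
either end.

## The simulator: what it emulates and what it does not

`simulate_sts()` / `simulate_tug()` build a piecewise-analytic motion:
minimum-jerk quintic transitions `s(τ) = 10τ³ − 15τ⁴ + 6τ⁵` for rises
(default H = 0.30 m over 0.6 s) and descents (1.0 s), short holds (0.2 s —
the tests are performed as quickly as possible, so dwell is brief), 0.5 s
of quiet sitting at both ends, and for TUG a 3 m walk at 1 m/s with a
raised-cosine vertical bounce at twice the 2 Hz step frequency (two
vertical oscillations per stride, an integer number of cycles so walking
starts and ends at zero vertical velocity). The minimum-jerk closed-form
peak velocity `1.875·H/T = 0.94 m/s` lands inside the ~0.9–1.2 m/s range
reported for adults, which is the main reason this transition model was
chosen.

Sensor models: the IMU channel is the analytic acceleration at 128 Hz plus
white noise (SD 0.02 m/s²) and a bias `b₀ + b₁t` (0.005 m/s²,
0.0005 m/s³) — the minimal model producing the quadratic/cubic
displacement drift the corrections exist to remove. The position channel is
the analytic displacement at ~30 Hz with per-sample clock jitter
(SD 5 ms, clamped to 45% of the interval so timestamps stay ordered) plus
5 mm white noise. The noise magnitudes are calibration choices, not
hardware claims: they were set once so that the simulated device agreement
lands in the empirically reported regime for this class of equipment
(displacement NRMSE of a few percent for STS, ~15–20% for single-span-ZDU
TUG, correlation ordering displacement > velocity > acceleration). Head
versus lower-back placement is represented only by different noise/bias
configurations, not different motion models.

Not emulated: joint-level biomechanics, ground-reaction forces, 3-D
rotation, turning dynamics (the turn is an AP plateau), or medio-lateral
motion. Passing tests therefore demonstrate the *pipeline's* correctness
under a realistic signal model, not the fidelity of any particular
hardware; real recordings add orientation-estimation error and soft-tissue
artifact that the simulator deliberately omits.

## Numerical choices and tolerances

- **Filter edges.** Zero-phase filtering uses odd-reflection padding of
  three settling lengths (at least ~100 samples) per end, so the
  zero-state start-up transients of both passes die inside the padding even
  on short (~11 s) records.
- **Integration accuracy.** Trapezoid integration of 128 Hz samples is
  second-order accurate, but the motion model's jerk steps at segment
  boundaries generally fall *between* samples; each such kink contributes
  an O(h²·|Δjerk|) error, accumulating to ~1 cm of displacement over an
  11 s STS trial. Tests assert 2 cm, the scheme's actual bound, and the
  drift correction absorbs this in practice.
- **Differentiation accuracy.** Central differences at 30 Hz carry a
  `dt²/6·|jerk|` truncation error — about 1.6% of the velocity peak at the
  jerk extremes, though the *peak* velocity itself is accurate to ~0.2%
  because jerk vanishes there. Feature tests use the 2% peak-value
  tolerance; pointwise profile tests use 2.5%.
- **Filter-response validation.** Digital Butterworth magnitudes follow the
  analytic `(1+(f/f_c)^{2n})^{-1/2}` only where bilinear-transform warping
  is negligible; at 128 Hz the response at `2·f_c = 10 Hz` is ~6% below
  the analog curve from warping alone. Gain tests therefore probe each
  specification at a sampling rate fast enough (1024 Hz for the low-pass)
  that warping stays below the 2% tolerance.
- **Degenerate inputs.** Constant signals are rejected by contact
  detection, phase detection, correlation and NRMSE with explicit errors;
  a single ZDU contact degenerates to removing one offset; zero-duration
  simulator segments (e.g. a TUG with no walk) are dropped, so the
  degenerate TUG collapses to a single STS cycle.
- **Ties.** Lag ties are broken toward the smallest absolute lag;
  equal-depth minima within a seated region resolve by the velocity-sign
  rule above.

## Problem sizes

The validation suite simulates trials of ~11 s (STS) and ~9.6 s (TUG) at
the native 128 Hz / 30 Hz rates and analyses them at 30 Hz (~330 samples
per channel). Stochastic properties use 50–200 seeded replicates; the
acceptance script uses 20 trials per task, mirroring a 20-participant
condition. These sizes keep the full suite in the tens of seconds while
leaving every statistic estimable.

## Known limitations

- AP/ML drift correction for the inertial channel is out of scope: no
  chair-contact analogue constrains horizontal position, so the package
  (like the measurement design it implements) restricts device agreement
  to the vertical axis; the simulator's AP truth supports only qualitative
  comparison of the position channel against the 3 m walk geometry.
- Contact timing under noise is limited by the slow minimum-jerk tails:
  where the true velocity sinks below the noise floor, the velocity-sign
  refinement wanders by a few samples (~0.1–0.3 s at the default noise),
  which is visible in the stochastic test tolerances.
- The TUG is treated as exactly one rise/descent cycle; multi-cycle TUG
  recordings (false starts) raise an ambiguity error with diagnostics
  rather than guessing.

## A complete run

```{r pipeline}
trial <- simulate_sts(simulation_config("STS", seed = 11))
report <- run_pipeline(trial)
report
```

```{r features}
kin <- report$kinematics$position
detect_phases(kin)
```
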