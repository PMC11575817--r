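---
title: "Methods: simulating and judging the validity of barbell-velocity devices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and judging the validity of barbell-velocity devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Velocity-based training (VBT) prescribes and monitors resistance training
through barbell velocity, most often the mean concentric velocity (MV) of a
repetition. Practical measurement systems — linear transducers and
smartphone apps — must be validated against a gold-standard 3D motion-capture
criterion before their readings can be trusted. A validity study of this kind
produces, per device and exercise, estimates of fixed and proportional bias
(intercept and slope of device vs criterion), random error (R²), absolute
precision (RMSE), standardized mean bias (SMB), and counts of missed and
ghost repetitions; equivalence to an accepted practical reference device is
then judged with a region of practical equivalence (ROPE).

`vbtvalid` implements this complete workflow as a reusable, tested pipeline,
exercised end to end on synthetic data with known ground truth. Every stage —
cohort, trajectories, criterion signal processing, device observations,
pairing, model fits, equivalence classification — is a package function, so
the same machinery that is validated on simulations can re-analyze a real
per-repetition dataset (`run_external()`).

## The synthetic cohort and protocol

`simulate_cohort()` draws body mass and relative one-repetition maxima (1RM)
from truncated normal distributions matching published characteristics of
competitive powerlifters (body mass 83.4 ± 19.8 kg; relative 1RM 2.32 ± 0.43,
1.46 ± 0.36, and 2.71 ± 0.48 kg·kg⁻¹ for squat, bench press, and deadlift).
Sampling is by rejection, jointly truncating each relative 1RM, body mass,
and the implied absolute 1RM to the published minima–maxima, so no simulated
lifter is stronger or lighter than the reference cohort allows. The loading
protocol is the standard ascending ladder: one repetition each at
45–90% 1RM in 5% steps, loads rounded to the nearest 2.5 kg (ties half up).

## Trajectory generation

Each attempt is a vertical barbell position series at 200 Hz with the phase
order of the exercise: squat, lowering then concentric; bench press,
lowering, chest pause, concentric; deadlift, concentric first, then lowering.
The concentric target MV comes from a linear load–velocity relationship
anchored at 45% and 90% 1RM; the defaults (squat 0.90 → 0.30, bench
0.75 → 0.17, deadlift 0.80 → 0.25 m·s⁻¹) span the ~0.1–1.0 m·s⁻¹ range seen
in powerlifting loading protocols and are configurable
(`trajectory_config()`). These defaults are plausible placeholders: real
lifters' individual load–velocity profiles vary, and no per-lifter profile
variation is simulated beyond the measurement chain.

The concentric velocity profile is a plateau with quarter-sine ramps, which
gives exact closed-form displacement, near-zero boundary velocities, and —
after trapezoidal integration on the sample grid — a generated phase whose
displacement equals the nominal range of motion to machine precision. Phase
durations are rounded to whole samples and the reported ground-truth MV is
range of motion divided by the sampled concentric duration, so the generator
is exactly self-consistent. An optional sticking-region dip multiplies
mid-concentric velocity by a Gaussian notch of configurable depth, with the
profile renormalized to conserve displacement.

Two numerical choices deserve emphasis, because the repetition detector
defines a repetition as a maximal run of samples with filtered vertical
velocity above 0.02 m·s⁻¹:

* **Boundary anchoring.** If a concentric phase borders perfect stillness,
  the zero-phase low-pass filter smears its onset/offset across ~10 ms and
  biases the measured MV of fast lifts by over 1% of its true value. Real
  lifts do not border stillness: the squat concentric follows the descent and
  ends in a post-lockout settle; the bench press begins with the bar sinking
  out of the chest pause and ends with lockout recoil; the deadlift starts
  after a slack-pull dip and ends in the lowering phase. The generator
  includes these small counter-movements (0.5–2.2 cm, far below the 10 cm
  repetition threshold), which pin the threshold crossings to the true phase
  boundaries.
* **Ramp-time rule.** The quarter-sine ramp time is `min(Rmax, max(0.02,
  c/Tc))` seconds with per-exercise constants (squat c = 0.08, Rmax = 0.10;
  bench 0.05, 0.085; deadlift 0.08, 0.085): slow lifts get steep ramps so the
  sub-threshold fraction of the phase stays negligible, fast lifts get soft
  ramps whose spectral content stays well inside the 10 Hz filter passband.
  These constants were fixed once against the default 3 × 10 exercise-by-load
  grid; with them, pipeline MV agrees with ground truth to within 0.2%
  everywhere on that grid (0.5% is the package's acceptance bound), at every
  sticking-dip depth up to 0.5.

Gaussian position noise (default SD 0.5 mm, a typical marker-reconstruction
jitter) is added last and never enters the reported ground truth.

What the generator does **not** emulate: video capture and camera geometry,
plate-diameter scaling, tether-angle effects, barbell tilt, horizontal bar
path (the x/y channels carry only noise), lifter fatigue, or failed
repetitions. Device error is modelled phenomenologically at the MV level, so
passing tests show the statistical pipeline recovers known MV-level effect
structure — not that any particular physical device behaves this way.

## Device observation model

`simulate_device()` observes each performed repetition as
`(α + u0ᵢ) + (β + u1ᵢ)·MV + ε`, with subject-level random effects `(u0, u1)`
drawn once per subject from a bivariate normal (SDs and correlation set in
`device_profile()`) and residual noise `ε ~ N(0, σ²)`. Readings are floored
at 0.01 m·s⁻¹ since devices report positive velocities. Missed repetitions
are dropped with a constant per-repetition probability, and ghost
repetitions (spurious detections, e.g. unracking counted as a repetition)
are appended per set with a constant per-set probability; neither is
velocity-dependent, a deliberate simplification. The default device set
(`default_devices()`) spans a low-error transducer-like reference, a
near-equivalent app, an app with marked proportional bias, and a noisy app
with a 10% missed-repetition rate — the qualitative spread reported for
commercial systems.

## Criterion processing

`process_attempt()` reproduces standard motion-capture processing: a
fourth-order Butterworth low-pass at 10 Hz applied forward and backward
(phase-shift correction; two-pass gain `1/(1+(f/10)^8)`), differentiation by
central differences, repetition detection by the dual threshold (velocity
strictly above 0.02 m·s⁻¹, net vertical displacement at least 0.10 m), and
mean velocity as displacement over duration. "Distance" is vertical
displacement — the thresholds refer to lifting height — and only upward
segments count, since the concentric phase is defined by raising the load.
Filter edges use odd (point-reflected) extension of three warm-up lengths
with mean-centring, and attempts include at least 0.5 s of quiet margin.
Threshold comparisons are strict for velocity and inclusive for
displacement; these are fixed conventions, as is the deterministic
resolution rule (`resolve_reps()`: keep the largest-displacement segments,
earlier start on ties) that replaces interactive cross-checking when extra
movements survive thresholding.

## The validity models

Both inference models are Bayesian linear mixed models with correlated
random intercepts and slopes per lifter, sampled with JAGS (4 chains,
500 adaptation + 1000 burn-in + 1000 kept draws by default; split-R̂ < 1.01
and effective sample sizes are recorded, and a failed gate flags — never
hides — the fit):

* **Calibration model** (`fit_calibration()`): practical MV as a function of
  criterion MV. The group intercept and slope measure fixed and proportional
  bias; Bayesian R² (`compute_r2()`) and posterior-predictive RMSE
  (`compute_rmse()`) measure random error and absolute precision.
* **Mean-bias model** (`fit_mean_bias()`): each repetition contributes a
  criterion row and a device row, and MV is modelled on a 0/1 source dummy;
  the source effect δ is the mean difference, and SMB = δ divided by the SD
  of the criterion MVs in the analyzed dataset (`compute_smb()`), a
  criterion-anchored standardizer chosen because the true standardizer used
  in practice varies between studies; alternatives can be passed explicitly.

Responses (and the regressor, in the calibration model) are centred and
scaled by the criterion mean and SD before sampling; coefficients are
back-transformed to natural units. On the standardized scale the priors are
weakly informative: Normal(0, 1) on fixed effects, half-Normal(1) on the
residual and random-effect SDs, and a Beta(2, 2) prior on the mapped
random-effect correlation (the two-dimensional equivalent of an LKJ(2)
prior). Subject effects use a non-centred (Cholesky) parametrization, which
mixes far better under Gibbs sampling when random-effect SDs are small, and
the JAGS `glm` module provides block updates for the conjugate sub-graphs.
RMSE uses conditional-mean predictions without a residual draw (adding one
would inflate the posterior mean toward √2·σ); a `ppc_noise` switch exposes
the alternative.

## Equivalence against a practical reference

For each statistic, the ROPE is anchored at the perfect value (intercept 0,
slope 1, R² 1, RMSE 0, SMB 0) and sized by the reference device's posterior:
the 95% HDI limit farther from the perfect value sets the region
(`build_rope()`). Intercept, slope, and SMB get symmetric two-sided regions;
R² and RMSE are boundary-perfect (R² ≤ 1, RMSE ≥ 0), which forces one-sided
regions `[lower limit, 1]` and `[0, upper limit]`. ROPE bounds are
inclusive, direction comparisons strict — measure-zero conventions fixed for
reproducibility. A label requires 95% posterior support: `likely_equivalent`
at membership ≥ 0.95, `likely_different` at ≤ 0.05 or when one outside
direction reaches 0.95, otherwise `unclear` (0.945 is `unclear`). HDIs are
computed as the shortest window of sorted draws.

By construction the reference is always equivalent to itself. A consequence
worth knowing: a device that merely *ties* the reference can be judged
`unclear` or even `likely_different` on R²/RMSE when the reference posterior
is very narrow — the procedure is anchored to the reference's demonstrated
precision, not to an absolute error budget.

## Problem sizes and reproducibility

The package's own acceptance checks run the kinematics oracle on the full
noiseless 3 × 10 grid; parameter recovery with 20 lifters × 30 repetitions
over 20 seeded replicates at reduced sampler settings (2 chains,
600 burn-in, 500 kept — sizes chosen so the whole suite stays comfortably
interactive); and the discrimination study at the full default cohort of 20
lifters across all three exercises and three seeds. Every stochastic stage
derives its stream from one integer seed; identical configurations and seeds
reproduce studies byte for byte, including the MCMC draws.

## Known limitations

* Device error is linear in true MV with Gaussian residuals; no
  heteroscedasticity, outlier mixtures, or velocity-dependent missingness
  (plausible for camera-based apps) are simulated.
* Order-based repetition pairing is exact for single-repetition sets (the
  simulated protocol); multi-repetition sets rely on detection order.
* The equivalence procedure applies no multiplicity adjustment across the
  five statistics, matching field practice.
* Sampler settings trade precision for time; the convergence gate (split-R̂
  < 1.01) occasionally flags small-data fits, whose summaries are then
  reported with the flag set.
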