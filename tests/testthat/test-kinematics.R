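make_traj <- function(z, fs = 200) {
  n <- length(z)
  structure(data.frame(time_s = (seq_len(n) - 1) / fs, x_m = 0, y_m = 0,
                       z_m = z),
            class = c("vbt_trajectory", "data.frame"), sampling_rate = fs)
}

sine_amplitude <- function(x, t, f) {
  # least-squares amplitude of the f-Hz component
  fit <- lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

test_that("zero-phase filter passes DC and matches the analytic two-pass gain", {
  tr <- make_traj(rep(1.234, 800))
  expect_equal(lowpass_filter(tr)$z_m, tr$z_m, tolerance = 1e-9)

  fs <- 200
  t <- (0:(8 * fs)) / fs
  # 1 Hz: analytic two-pass gain 1/(1 + 0.1^8), i.e. amplitude preserved
  tr1 <- make_traj(0.1 * sin(2 * pi * 1 * t), fs)
  f1 <- lowpass_filter(tr1)
  interior <- t > 1 & t < max(t) - 1
  g1 <- sine_amplitude(f1$z_m[interior], t[interior], 1) / 0.1
  expect_equal(g1, 1 / (1 + 0.1^8), tolerance = 0.01)

  # 50 Hz: analytic two-pass gain 1/(1 + 5^8) ~ 2.6e-6; allow edge effects
  # within a factor of 10 on interior samples
  tr50 <- make_traj(0.1 * sin(2 * pi * 50 * t), fs)
  f50 <- lowpass_filter(tr50)
  g50 <- sine_amplitude(f50$z_m[interior], t[interior], 50) / 0.1
  expect_lt(g50, 10 / (1 + 5^8))
})

test_that("filtering is idempotent in the passband", {
  fs <- 200
  t <- (0:(8 * fs)) / fs
  tr <- make_traj(0.2 * sin(2 * pi * 1 * t), fs)
  once <- lowpass_filter(tr)
  twice <- lowpass_filter(once)
  interior <- t > 1 & t < max(t) - 1
  a1 <- sine_amplitude(once$z_m[interior], t[interior], 1)
  a2 <- sine_amplitude(twice$z_m[interior], t[interior], 1)
  expect_lt(abs(a2 / a1 - 1), 0.02)
})

test_that("filter rejects invalid cutoffs and too-short inputs", {
  tr <- make_traj(rep(1, 800))
  expect_error(lowpass_filter(tr, cutoff = 100), "Nyquist")
  expect_error(lowpass_filter(make_traj(rep(1, 30)), cutoff = 10), "warm-up")
})

test_that("differentiation is exact on ramps and accurate on sinusoids", {
  fs <- 200
  t <- (0:(2 * fs)) / fs
  v <- differentiate(make_traj(0.3 * t, fs))
  expect_equal(v, rep(0.3, length(t)), tolerance = 1e-10)
  expect_equal(differentiate(make_traj(rep(0.7, 400), fs)),
               rep(0, 400))
  z <- sin(2 * pi * 0.5 * t)
  v <- differentiate(make_traj(z, fs))
  truth <- 2 * pi * 0.5 * cos(2 * pi * 0.5 * t)
  # central differences: truncation error bounded by (h^2/6) * max|z'''|
  bound <- (1 / fs)^2 / 6 * (2 * pi * 0.5)^3
  expect_lt(max(abs(v - truth)[2:(length(t) - 1)]), 1.05 * bound)
})

test_that("rep detection applies both thresholds with a closed-form oracle", {
  fs <- 200
  # all-zero velocity: no segments
  empty <- detect_reps(rep(0, 400), rep(1, 400), (0:399) / fs)
  expect_equal(nrow(empty), 0)

  # half-sine velocity pulse, peak 0.6 m/s over 1 s, quiet margins
  t <- (0:(3 * fs)) / fs
  vpeak <- 0.6
  v <- ifelse(t >= 1 & t <= 2, vpeak * sin(pi * (t - 1)), 0)
  z <- 1 + (vpeak / pi) * ifelse(t < 1, 0, ifelse(t > 2, 2,
                                                  1 - cos(pi * (t - 1))))
  segs <- detect_reps(v, z, t)
  expect_equal(nrow(segs), 1)
  # independent oracle: analytic position/time at the sampled threshold
  # crossings of the half-sine (first/last samples with v > 0.02)
  above <- which(v > 0.02)
  ts <- t[min(above)]; te <- t[max(above)]
  disp <- (vpeak / pi) * (cos(pi * (ts - 1)) - cos(pi * (te - 1)))
  expect_equal(segs$mean_velocity, disp / (te - ts), tolerance = 1e-9)
  # threshold truncation biases the measured MV slightly above the
  # full-pulse mean vpeak * 2 / pi, by ~3% at this peak velocity
  expect_gt(segs$mean_velocity, vpeak * 2 / pi)
  expect_lt(segs$mean_velocity / (vpeak * 2 / pi), 1.04)

  # a pulse with 5 cm displacement is filtered out by the 10 cm rule
  v_small <- ifelse(t >= 1 & t <= 2, 0.05 * pi / 2 * sin(pi * (t - 1)), 0)
  z_small <- 1 + 0.025 * ifelse(t < 1, 0, ifelse(t > 2, 2,
                                                 1 - cos(pi * (t - 1))))
  expect_equal(nrow(detect_reps(v_small, z_small, t)), 0)

  # sub-threshold drift never opens a segment even over large displacement
  drift <- rep(0.015, 30 * fs)
  z_d <- cumsum(drift) / fs
  expect_equal(nrow(detect_reps(drift, z_d, seq_along(drift) / fs)), 0)
})

test_that("detected segments are sorted, non-overlapping and self-consistent", {
  fs <- 200
  t <- (0:(10 * fs)) / fs
  # three separated pulses of varying size
  v <- numeric(length(t))
  for (s in c(1, 4, 7)) {
    sel <- t >= s & t <= s + 1.2
    v[sel] <- v[sel] + (0.2 + s / 10) * sin(pi * (t[sel] - s) / 1.2)
  }
  z <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2)) / fs
  segs <- detect_reps(v, z, t)
  expect_gte(nrow(segs), 2)
  expect_true(all(diff(segs$start_time) > 0))
  expect_true(all(segs$end_time[-nrow(segs)] <= segs$start_time[-1]))
  expect_equal(segs$mean_velocity * segs$duration, segs$displacement,
               tolerance = 1e-12)
})

test_that("multiple detections resolve by displacement with earlier-start ties", {
  segs <- structure(data.frame(
    start_time = c(1, 4, 7), end_time = c(2, 5, 8), duration = 1,
    displacement = c(0.48, 0.12, 0.47),
    mean_velocity = c(0.48, 0.12, 0.47)
  ), class = c("vbt_segments", "data.frame"))
  kept <- resolve_reps(segs, 1)
  expect_equal(kept$displacement, 0.48)
  # count equals expected: unchanged
  expect_equal(resolve_reps(segs, 3)$displacement, segs$displacement)
  # exact tie: earlier segment wins
  tie <- segs
  tie$displacement <- c(0.47, 0.47, 0.12)
  expect_equal(resolve_reps(tie, 1)$start_time, 1)
  # shortfall flagged with a warning
  expect_warning(short <- resolve_reps(segs, 5), "expected 5")
  expect_true(attr(short, "shortfall"))
})

test_that("the criterion pipeline recovers noiseless and noisy attempts", {
  cfg <- trajectory_config("squat", rom = 0.5, noise_sd = 0)
  tr <- simulate_trajectory("squat", 0.75, cfg, seed = 1)  # MV 0.5, 1.0 s
  obs <- process_attempt(tr)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$mean_velocity, 0.5, tolerance = 0.005)

  # 1 mm white position noise: same rep count, MV within 2% of truth
  cfg_n <- trajectory_config("squat", rom = 0.5, noise_sd = 0.001)
  errs <- vapply(1:30, function(s) {
    trn <- simulate_trajectory("squat", 0.75, cfg_n, seed = s)
    on <- process_attempt(trn)
    expect_equal(nrow(on), 1)
    on$mean_velocity / 0.5 - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.02)
})

test_that("an unrack bump below 10 cm never becomes a repetition", {
  fs <- 200
  cfg <- trajectory_config("squat", rom = 0.5, noise_sd = 0)
  tr <- simulate_trajectory("squat", 0.70, cfg, seed = 2)
  # prepend a 5 cm unrack bump (up) followed by quiet standing
  tb <- (0:(0.4 * fs)) / fs
  vb <- 0.05 * (pi / (2 * 0.4)) * sin(pi * tb / 0.4)
  zb <- cumsum(c(0, (vb[-1] + vb[-length(vb)]) / 2)) / fs
  pre <- c(rep(0, fs), zb, rep(0.05, fs))
  z <- c(tr$z_m[1] - 0.05 + pre, tr$z_m[-1])
  bumped <- make_traj(z, fs)
  attr(bumped, "exercise") <- "squat"
  obs <- process_attempt(bumped)
  expect_equal(nrow(obs), 1)
  expect_equal(obs$mean_velocity,
               process_attempt(tr)$mean_velocity, tolerance = 1e-6)
})
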