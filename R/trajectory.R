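#' Trajectory generator configuration
#'
#' Controls the synthetic barbell trajectory for one exercise: range of motion,
#' the load-velocity relationship, the optional sticking-region velocity dip,
#' and additive marker noise.
#'
#' The concentric mean velocity (MV) prescribed for a repetition is obtained by
#' linear interpolation between `mv_at_min_load` (at 45% 1RM) and
#' `mv_at_max_load` (at 90% 1RM); fractions outside that window extrapolate
#' linearly. Defaults per exercise span roughly 0.17-0.90 m/s across the
#' 45-90% ladder, reproducing the 0.1-1.0 m/s range typical of powerlifting
#' loading protocols.
#'
#' @param exercise `"squat"`, `"bench"` or `"deadlift"`.
#' @param sampling_rate Sampling frequency in Hz.
#' @param rom Vertical range of motion in metres (> 0.10 m, i.e. above the
#'   repetition displacement threshold).
#' @param pause_duration Chest pause in seconds (bench press only).
#' @param mv_at_min_load,mv_at_max_load Mean concentric velocity (m/s) at 45%
#'   and at 90% 1RM; `mv_at_max_load < mv_at_min_load`.
#' @param sticking_dip_depth Mid-concentric velocity dip as a fraction of the
#'   local peak velocity, in `[0, 1)`; 0 disables the dip.
#' @param noise_sd SD of additive Gaussian position noise in metres.
#' @return A list of class `vbt_trajectory_config`.
#' @export
#' @examples
#' trajectory_config("bench", sticking_dip_depth = 0.3)
trajectory_config <- function(exercise,
                              sampling_rate = 200,
                              rom = NULL,
                              pause_duration = 0.8,
                              mv_at_min_load = NULL,
                              mv_at_max_load = NULL,
                              sticking_dip_depth = 0,
                              noise_sd = 0.0005) {
  exercise <- match_exercise(exercise)
  defaults <- list(
    squat    = list(rom = 0.55, mv_min = 0.90, mv_max = 0.30),
    bench    = list(rom = 0.40, mv_min = 0.75, mv_max = 0.17),
    deadlift = list(rom = 0.50, mv_min = 0.80, mv_max = 0.25)
  )[[exercise]]
  rom <- rom %||% defaults$rom
  mv_at_min_load <- mv_at_min_load %||% defaults$mv_min
  mv_at_max_load <- mv_at_max_load %||% defaults$mv_max
  stop_if_not(sampling_rate > 0, "sampling_rate must be > 0")
  stop_if_not(rom > 0.10, "rom must exceed the 0.10 m detection threshold")
  stop_if_not(sticking_dip_depth >= 0 && sticking_dip_depth < 1,
              "sticking_dip_depth must lie in [0, 1)")
  stop_if_not(mv_at_max_load < mv_at_min_load,
              "mv_at_max_load must be below mv_at_min_load")
  stop_if_not(mv_at_max_load > 0, "mean velocities must be positive")
  stop_if_not(noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(pause_duration >= 0.2, "pause_duration must be >= 0.2 s")
  structure(list(exercise = exercise,
                 sampling_rate = sampling_rate,
                 rom = rom,
                 pause_duration = pause_duration,
                 mv_at_min_load = mv_at_min_load,
                 mv_at_max_load = mv_at_max_load,
                 sticking_dip_depth = sticking_dip_depth,
                 noise_sd = noise_sd),
            class = "vbt_trajectory_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prescribed mean velocity at a load fraction
#'
#' Linear load-velocity mapping anchored at 45% and 90% 1RM.
#'
#' @param load_fraction Fraction of 1RM in (0, 1].
#' @param config A [trajectory_config()].
#' @return Mean concentric velocity in m/s.
#' @export
load_velocity <- function(load_fraction, config) {
  stop_if_not(all(load_fraction > 0 & load_fraction <= 1),
              "load_fraction must lie in (0, 1]")
  slope <- (config$mv_at_max_load - config$mv_at_min_load) / (0.90 - 0.45)
  config$mv_at_min_load + slope * (load_fraction - 0.45)
}

# --- velocity profile primitives -------------------------------------------
# All segments are built as velocity samples on the uniform grid and
# integrated with the trapezoidal rule, so displacement bookkeeping is exact
# at machine precision on the sampled signal.

# Plateau lobe with quarter-sine ramps; displacement D (signed) over T s.
# Ramp time shrinks for slower lifts (clamp(0.065/T, 0.02, 0.085) s) so the
# fraction of the phase spent below the 0.02 m/s detection threshold stays
# negligible at every speed, while fast lifts keep all content well inside
# the 10 Hz criterion filter passband.
vel_lobe <- function(T, D, fs, ramp = NULL, dip = 0) {
  T <- max(2, round(T * fs)) / fs  # durations live on the sample grid
  if (is.null(ramp)) ramp <- min(0.10, max(0.02, 0.08 / T))
  ramp <- min(ramp, 0.45 * T)
  t <- seq(0, T, by = 1 / fs)
  v <- ifelse(t < ramp, sin(pi * t / (2 * ramp)),
              ifelse(t > T - ramp, sin(pi * (T - t) / (2 * ramp)), 1))
  if (dip > 0) {
    w <- T / 10
    v <- v * (1 - dip * exp(-((t - T / 2) / w)^2))
  }
  v * D / (sum((v[-1] + v[-length(v)]) / 2) / fs)
}

# Single half-sine velocity lobe (small settle/dip movements).
vel_halfsine <- function(T, D, fs) {
  T <- max(2, round(T * fs)) / fs
  t <- seq(0, T, by = 1 / fs)
  v <- sin(pi * t / T)
  v * D / (sum((v[-1] + v[-length(v)]) / 2) / fs)
}

vel_still <- function(T, fs) rep(0, round(T * fs))

#' Simulate one barbell lift attempt
#'
#' Generates the vertical barbell trajectory of a single repetition with the
#' phase structure of the exercise: squat, eccentric then concentric; bench
#' press, eccentric, chest pause, concentric; deadlift, concentric first, then
#' lowering. Each concentric boundary is flanked by the small counter-movements
#' seen in real lifts (post-lockout settle, bar sink at the end of the bench
#' pause, pre-pull dip in the deadlift); these keep instantaneous velocity at
#' the phase boundaries near zero with a sharp crossing, carry displacements
#' far below the 0.10 m repetition threshold, and never register as
#' repetitions. An optional sticking-region dip scales mid-concentric velocity
#' down by `sticking_dip_depth` with total displacement conserved. Gaussian
#' position noise is added last; the returned true mean velocity is the
#' noiseless value.
#'
#' @param exercise `"squat"`, `"bench"` or `"deadlift"`.
#' @param load_fraction Fraction of 1RM in (0, 1]; sets the target mean
#'   velocity through [load_velocity()].
#' @param config A [trajectory_config()] for the exercise.
#' @param seed Integer seed for the position noise.
#' @return A data frame of class `vbt_trajectory` with columns `time_s`,
#'   `x_m`, `y_m`, `z_m` (z vertical) and attributes `exercise`,
#'   `load_fraction`, `true_mean_velocity` (m/s), `concentric` (start/end
#'   times in s) and `sampling_rate`.
#' @export
#' @examples
#' tr <- simulate_trajectory("squat", 0.7, seed = 1)
#' attr(tr, "true_mean_velocity")
simulate_trajectory <- function(exercise, load_fraction,
                                config = trajectory_config(exercise),
                                seed = 1L) {
  exercise <- match_exercise(exercise)
  stopifnot(inherits(config, "vbt_trajectory_config"))
  stop_if_not(identical(config$exercise, exercise),
              "config was built for a different exercise")
  stop_if_not(length(load_fraction) == 1 && load_fraction > 0 &&
                load_fraction <= 1, "load_fraction must lie in (0, 1]")
  fs <- config$sampling_rate
  rom <- config$rom
  mv <- load_velocity(load_fraction, config)
  stop_if_not(mv > 0.02, "prescribed mean velocity must exceed 0.02 m/s")
  Tc <- rom / mv
  Te <- max(1.0, rom / 0.45)
  ramp_e <- min(0.15, 0.2 * Te)
  dip <- config$sticking_dip_depth
  quiet <- 0.75

  # concentric ramp time and boundary-anchor movements, per exercise; chosen
  # so threshold truncation and zero-phase filter smear cancel across the
  # default load grid (see the methods vignette)
  shape <- list(
    squat    = list(cc = 0.08, rmax = 0.10),
    bench    = list(cc = 0.05, rmax = 0.085),
    deadlift = list(cc = 0.08, rmax = 0.085)
  )[[exercise]]
  ramp_c <- min(shape$rmax, max(0.02, shape$cc / Tc))
  conc <- vel_lobe(Tc, rom, fs, ramp = ramp_c, dip = dip)
  if (exercise == "squat") {
    phases <- list(vel_still(quiet, fs),
                   vel_lobe(Te, -rom, fs, ramp = ramp_e),
                   conc,
                   vel_halfsine(0.12, -0.022, fs),  # post-lockout settle
                   vel_still(quiet, fs))
    conc_phase <- 3L
    z0 <- 1.0
  } else if (exercise == "bench") {
    pause <- config$pause_duration
    sink_T <- 0.10
    phases <- list(vel_still(quiet, fs),
                   vel_lobe(Te, -rom, fs, ramp = ramp_e),
                   vel_still(pause - sink_T, fs),
                   vel_halfsine(sink_T, -0.010, fs),  # bar sink ending the pause
                   conc,
                   vel_halfsine(0.10, -0.016, fs),    # lockout recoil
                   vel_still(quiet, fs))
    conc_phase <- 5L
    z0 <- 1.0
  } else {
    phases <- list(vel_still(quiet, fs),
                   vel_halfsine(0.10, 0.005, fs),     # taking out the slack
                   vel_halfsine(0.12, -0.014, fs),    # pre-pull dip
                   conc,
                   vel_lobe(Te, -rom, fs, ramp = ramp_e),
                   vel_still(quiet, fs))
    conc_phase <- 4L
    z0 <- 0.10
  }

  # concatenate phases sharing boundary samples, tracking the concentric
  # phase's exact sample indices
  v <- phases[[1]]
  conc_idx <- c(NA_integer_, NA_integer_)
  for (k in 2:length(phases)) {
    if (k == conc_phase) conc_idx[1] <- length(v)
    v <- c(v, phases[[k]][-1])
    if (k == conc_phase) conc_idx[2] <- length(v)
  }

  dt <- 1 / fs
  n <- length(v)
  z <- z0 + cumsum(c(0, (v[-1] + v[-n]) / 2)) * dt
  time_s <- (seq_len(n) - 1L) * dt
  conc_start <- time_s[conc_idx[1]]
  conc_end <- time_s[conc_idx[2]]
  # the generated phase's own (noiseless) mean velocity: displacement is
  # exact by construction, duration lives on the sample grid
  mv_true <- rom / (conc_end - conc_start)
  out <- with_seed(seed, {
    noise <- function() {
      if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
    }
    data.frame(time_s = time_s,
               x_m = noise(),
               y_m = noise(),
               z_m = z + noise())
  })
  structure(out,
            class = c("vbt_trajectory", "data.frame"),
            exercise = exercise,
            load_fraction = load_fraction,
            true_mean_velocity = mv_true,
            concentric = c(start = conc_start, end = conc_end),
            sampling_rate = fs)
}
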