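#' Reference anthropometrics for a competitive powerlifting cohort
#'
#' Distribution parameters (mean, SD, min, max) describing body mass and
#' relative one-repetition maxima (1RM, in kg per kg body mass) of a cohort of
#' competitive powerlifters. Values follow published sample characteristics of
#' mixed-sex national-level lifters. Relative 1RMs are multiplied by body mass
#' to obtain absolute 1RMs, so simulated strength scales realistically with
#' body size.
#'
#' @return A named list with elements `body_mass`, `squat`, `bench`,
#'   `deadlift`, each a numeric vector `c(mean, sd, min, max)`.
#' @export
#' @examples
#' cohort_anthropometrics()
cohort_anthropometrics <- function() {
  list(
    body_mass = c(mean = 83.4, sd = 19.8, min = 55.8, max = 147.7),
    squat     = c(mean = 2.32, sd = 0.43, min = 1.68, max = 3.46),
    bench     = c(mean = 1.46, sd = 0.36, min = 0.88, max = 2.28),
    deadlift  = c(mean = 2.71, sd = 0.48, min = 2.07, max = 3.88),
    absolute  = list(squat = c(min = 120, max = 310),
                     bench = c(min = 55, max = 230),
                     deadlift = c(min = 142.5, max = 360))
  )
}

# Truncated-normal sampling by rejection; exact and simple at these mild
# truncations (all bounds within ~2.5 SD of the mean).
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (sd < 0) stop("distribution SD must be non-negative", call. = FALSE)
  if (sd == 0) {
    stop_if_not(mean >= lower && mean <= upper,
                "degenerate distribution mean outside truncation bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of powerlifters
#'
#' Draws body mass and relative 1RMs from truncated normal distributions
#' (rejection sampling, truncated at the reference minima/maxima) and derives
#' absolute 1RMs as relative 1RM x body mass.
#'
#' @param n_subjects Number of lifters (>= 1).
#' @param seed Integer seed; the cohort is fully reproducible given the seed.
#' @param params Distribution parameters as returned by
#'   [cohort_anthropometrics()]. SDs may be set to 0 to obtain a cohort of
#'   identical average lifters.
#' @return A data frame of class `vbt_cohort` with columns `subject_id`,
#'   `body_mass`, `one_rm_squat`, `one_rm_bench`, `one_rm_deadlift` (kg).
#' @export
#' @examples
#' simulate_cohort(5, seed = 1)
simulate_cohort <- function(n_subjects, seed, params = cohort_anthropometrics()) {
  stop_if_not(is.numeric(n_subjects) && n_subjects >= 1,
              "n_subjects must be >= 1")
  needed <- c("body_mass", "squat", "bench", "deadlift")
  stop_if_not(all(needed %in% names(params)),
              "params must contain body_mass, squat, bench, deadlift")
  for (nm in needed) {
    p <- params[[nm]]
    stop_if_not(all(c("mean", "sd", "min", "max") %in% names(p)),
                sprintf("params$%s must have mean, sd, min, max", nm))
    if (p[["sd"]] < 0) {
      stop(sprintf("invalid distribution spec for '%s': sd must be >= 0", nm),
           call. = FALSE)
    }
  }
  n_subjects <- as.integer(n_subjects)
  abs_range <- params$absolute
  with_seed(seed, {
    draw_subject <- function() {
      # joint rejection: relative 1RMs and body mass are each truncated, and
      # the implied absolute 1RMs must also fall inside the reference ranges
      repeat {
        bm <- rtruncnorm_reject(1, params$body_mass[["mean"]],
                                params$body_mass[["sd"]],
                                params$body_mass[["min"]],
                                params$body_mass[["max"]])
        rel <- vapply(EXERCISES, function(ex) {
          p <- params[[ex]]
          rtruncnorm_reject(1, p[["mean"]], p[["sd"]], p[["min"]], p[["max"]])
        }, numeric(1))
        absolute <- rel * bm
        ok <- if (is.null(abs_range)) TRUE else {
          all(vapply(EXERCISES, function(ex) {
            absolute[[ex]] >= abs_range[[ex]][["min"]] &&
              absolute[[ex]] <= abs_range[[ex]][["max"]]
          }, logical(1)))
        }
        if (ok || all(vapply(c("body_mass", EXERCISES),
                             function(nm) params[[nm]][["sd"]] == 0,
                             logical(1)))) {
          return(c(bm, absolute))
        }
      }
    }
    draws <- t(vapply(seq_len(n_subjects), function(i) draw_subject(),
                      numeric(4)))
    out <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      body_mass = draws[, 1],
      one_rm_squat = draws[, 2],
      one_rm_bench = draws[, 3],
      one_rm_deadlift = draws[, 4],
      stringsAsFactors = FALSE
    )
    class(out) <- c("vbt_cohort", "data.frame")
    out
  })
}

#' Loading protocol specification
#'
#' A single-repetition ascending loading ladder expressed as fractions of the
#' 1RM, with barbell loads rounded to a plate increment.
#'
#' @param load_fractions Strictly increasing fractions of 1RM in (0, 1].
#'   Default: 45% to 90% in 5% steps (ten single repetitions).
#' @param reps_per_load Repetitions performed at each load.
#' @param load_rounding Plate rounding increment in kg.
#' @return A list of class `vbt_protocol`.
#' @export
protocol_spec <- function(load_fractions = seq(0.45, 0.90, by = 0.05),
                          reps_per_load = 1L,
                          load_rounding = 2.5) {
  stop_if_not(all(load_fractions > 0 & load_fractions <= 1),
              "load fractions must lie in (0, 1]")
  stop_if_not(all(diff(load_fractions) > 0),
              "load fractions must be strictly increasing")
  stop_if_not(reps_per_load >= 1, "reps_per_load must be >= 1")
  stop_if_not(load_rounding > 0, "load_rounding must be > 0")
  structure(list(load_fractions = load_fractions,
                 reps_per_load = as.integer(reps_per_load),
                 load_rounding = load_rounding),
            class = "vbt_protocol")
}

#' Absolute barbell loads for a lifter under a loading protocol
#'
#' @param subject One row of a [simulate_cohort()] data frame, or a single
#'   numeric 1RM in kg.
#' @param exercise One of `"squat"`, `"bench"`, `"deadlift"` (ignored when
#'   `subject` is numeric).
#' @param protocol A [protocol_spec()].
#' @return Numeric vector of barbell loads (kg), one per load fraction,
#'   rounded to the protocol increment with ties rounding half up.
#' @export
#' @examples
#' protocol_loads(200, protocol = protocol_spec())
protocol_loads <- function(subject, exercise = NULL, protocol = protocol_spec()) {
  stopifnot(inherits(protocol, "vbt_protocol"))
  if (is.numeric(subject)) {
    one_rm <- subject[[1]]
  } else {
    exercise <- match_exercise(exercise)
    col <- paste0("one_rm_", exercise)
    stop_if_not(col %in% names(subject),
                sprintf("subject has no 1RM for '%s'", exercise))
    one_rm <- subject[[col]][[1]]
  }
  stop_if_not(is.finite(one_rm) && one_rm > 0, "1RM must be positive")
  round_to_increment(protocol$load_fractions * one_rm, protocol$load_rounding)
}
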