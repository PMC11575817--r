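#' Measurement device error profile
#'
#' Phenomenological observation model for a practical velocity measurement
#' device (linear transducer or smartphone app). Observed mean velocity for
#' subject i is `(alpha + u0_i) + (beta + u1_i) * true_mv + e`, with
#' subject-level random effects `(u0, u1)` drawn once per subject from a
#' bivariate normal with SDs `re_sd` and correlation `re_cor`, and residual
#' noise `e ~ N(0, sigma^2)`. Repetitions are dropped (status `"missed"`)
#' with probability `miss_prob`, and spurious detections (status `"ghost"`,
#' e.g. unracking counted as a repetition) are appended per set with
#' probability `ghost_prob`.
#'
#' @param device_id Device label.
#' @param alpha Fixed bias intercept (m/s).
#' @param beta Proportional bias slope (dimensionless; 1 = none).
#' @param sigma Residual SD (m/s, >= 0).
#' @param re_sd Length-2 SDs of the subject-level (intercept, slope) random
#'   effects.
#' @param re_cor Correlation of the random effects, in `[-1, 1]`.
#' @param miss_prob Per-repetition probability of a missed repetition.
#' @param ghost_prob Per-set probability of a ghost repetition.
#' @return A list of class `vbt_device`.
#' @export
#' @examples
#' device_profile("lt", alpha = 0.01, beta = 0.99, sigma = 0.02)
device_profile <- function(device_id,
                           alpha = 0, beta = 1, sigma = 0,
                           re_sd = c(0, 0), re_cor = 0,
                           miss_prob = 0, ghost_prob = 0) {
  stop_if_not(sigma >= 0, "sigma must be >= 0")
  stop_if_not(length(re_sd) == 2 && all(re_sd >= 0),
              "re_sd must be two non-negative SDs")
  stop_if_not(abs(re_cor) <= 1, "re_cor must lie in [-1, 1]")
  stop_if_not(miss_prob >= 0 && miss_prob <= 1, "miss_prob must lie in [0, 1]")
  stop_if_not(ghost_prob >= 0 && ghost_prob <= 1, "ghost_prob must lie in [0, 1]")
  re_cov <- diag(re_sd) %*% matrix(c(1, re_cor, re_cor, 1), 2) %*% diag(re_sd)
  structure(list(device_id = device_id, alpha = alpha, beta = beta,
                 sigma = sigma, re_sd = re_sd, re_cor = re_cor,
                 re_cov = re_cov, miss_prob = miss_prob,
                 ghost_prob = ghost_prob),
            class = "vbt_device")
}

#' Simulate device observations for performed repetitions
#'
#' @param true_reps Data frame with one row per performed repetition:
#'   `subject_id`, `exercise`, `load_pct`, `set_index`, `rep_index`, and
#'   `true_mv` (noiseless criterion mean velocity, m/s).
#' @param profile A [device_profile()].
#' @param seed Integer seed; subject random effects, residuals and
#'   missed/ghost outcomes are reproducible given the seed.
#' @return A data frame in the repetition-observation schema: `subject_id`,
#'   `exercise`, `load_pct`, `set_index`, `rep_index`, `device_id`,
#'   `mean_velocity` (NA unless `status == "ok"`), `status`.
#' @export
simulate_device <- function(true_reps, profile, seed = 1L) {
  stopifnot(inherits(profile, "vbt_device"))
  needed <- c("subject_id", "exercise", "load_pct", "set_index", "rep_index",
              "true_mv")
  stop_if_not(all(needed %in% names(true_reps)),
              paste("true_reps must have columns:", paste(needed, collapse = ", ")))
  with_seed(seed, {
    subjects <- unique(true_reps$subject_id)
    u <- MASS::mvrnorm(length(subjects), mu = c(0, 0), Sigma = profile$re_cov)
    u <- matrix(u, ncol = 2)
    rownames(u) <- subjects
    n <- nrow(true_reps)
    idx <- match(true_reps$subject_id, subjects)
    obs_mv <- (profile$alpha + u[idx, 1]) +
      (profile$beta + u[idx, 2]) * true_reps$true_mv +
      stats::rnorm(n, 0, profile$sigma)
    # devices report strictly positive velocities; noise excursions below
    # zero (possible only for slow reps on very noisy devices) floor at a
    # minimal reading
    obs_mv <- pmax(obs_mv, 0.01)
    missed <- stats::runif(n) < profile$miss_prob
    out <- data.frame(
      subject_id = true_reps$subject_id,
      exercise = true_reps$exercise,
      load_pct = true_reps$load_pct,
      set_index = true_reps$set_index,
      rep_index = true_reps$rep_index,
      device_id = profile$device_id,
      mean_velocity = ifelse(missed, NA_real_, obs_mv),
      status = ifelse(missed, "missed", "ok"),
      stringsAsFactors = FALSE
    )
    # ghost repetitions: spurious extra detections appended per set
    sets <- unique(out[c("subject_id", "exercise", "load_pct", "set_index")])
    ghost <- stats::runif(nrow(sets)) < profile$ghost_prob
    if (any(ghost)) {
      g <- sets[ghost, , drop = FALSE]
      max_rep <- vapply(seq_len(nrow(g)), function(i) {
        sel <- out$subject_id == g$subject_id[i] &
          out$exercise == g$exercise[i] &
          out$load_pct == g$load_pct[i] &
          out$set_index == g$set_index[i]
        as.numeric(max(out$rep_index[sel]))
      }, numeric(1))
      ghosts <- data.frame(
        subject_id = g$subject_id, exercise = g$exercise,
        load_pct = g$load_pct, set_index = g$set_index,
        rep_index = max_rep + 1L, device_id = profile$device_id,
        mean_velocity = NA_real_, status = "ghost",
        stringsAsFactors = FALSE
      )
      out <- rbind(out, ghosts)
    }
    out <- out[order(out$subject_id, out$exercise, out$load_pct,
                     out$set_index, out$rep_index), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
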