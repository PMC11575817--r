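# Bayesian linear mixed models for method comparison, sampled with JAGS.
#
# Both models share one hierarchical structure: a group-level intercept and
# slope plus correlated subject-level deviations of each,
#   y_ij = (b0 + u0_i) + (b1 + u1_i) * x_ij + e_ij,
#   (u0, u1) ~ MVN(0, Sigma),  e ~ N(0, sigma^2).
# For the calibration model x is the criterion mean velocity; for the
# mean-bias model x is a 0/1 source dummy (criterion vs practical device).
# Responses (and, for the calibration model, x) are centred and scaled by
# the criterion mean/SD before sampling; weakly informative standardized
# priors are Normal(0,1) on the fixed effects, half-Normal(1) on all scales,
# and an LKJ(2)-equivalent Beta(2,2) prior on the random-effect correlation.

# Non-centered parametrization: subject effects are built from standard-
# normal latents through the Cholesky factor of the 2x2 covariance, which
# mixes far better under Gibbs sampling than the centered multivariate form
# when the random-effect SDs are small relative to the residual SD.
jags_lmm_string <- function(random_slope = TRUE) {
  if (random_slope) {
    "model {
      for (n in 1:N) {
        y[n] ~ dnorm((b0 + u[s[n], 1]) + (b1 + u[s[n], 2]) * x[n], tau_e)
      }
      for (j in 1:J) {
        z[j, 1] ~ dnorm(0, 1)
        z[j, 2] ~ dnorm(0, 1)
        u[j, 1] <- tau_u1 * z[j, 1]
        u[j, 2] <- tau_u2 * (rho * z[j, 1] + sqrt(1 - pow(rho, 2)) * z[j, 2])
      }
      b0 ~ dnorm(0, 1)
      b1 ~ dnorm(0, 1)
      sigma ~ dnorm(0, 1) T(0,)
      tau_e <- pow(sigma, -2)
      tau_u1 ~ dnorm(0, 1) T(0,)
      tau_u2 ~ dnorm(0, 1) T(0,)
      rho_raw ~ dbeta(2, 2)
      rho <- 2 * rho_raw - 1
    }"
  } else {
    "model {
      for (n in 1:N) {
        y[n] ~ dnorm((b0 + u[s[n], 1]) + b1 * x[n], tau_e)
      }
      for (j in 1:J) {
        z[j, 1] ~ dnorm(0, 1)
        u[j, 1] <- tau_u1 * z[j, 1]
        u[j, 2] <- 0
      }
      b0 ~ dnorm(0, 1)
      b1 ~ dnorm(0, 1)
      sigma ~ dnorm(0, 1) T(0,)
      tau_e <- pow(sigma, -2)
      tau_u1 ~ dnorm(0, 1) T(0,)
    }"
  }
}

#' Sampler settings for the mixed-model fits
#'
#' @param chains Number of MCMC chains (>= 2 for split-R-hat).
#' @param adapt Adaptation iterations.
#' @param warmup Burn-in iterations per chain.
#' @param draws Kept iterations per chain.
#' @return A list of class `vbt_sampler`.
#' @export
sampler_spec <- function(chains = 4L, adapt = 500L, warmup = 1000L,
                         draws = 1000L) {
  stop_if_not(chains >= 2, "need at least 2 chains for convergence diagnostics")
  stop_if_not(draws * chains >= 1000, "need at least 1000 kept draws in total")
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws)),
            class = "vbt_sampler")
}

run_jags_lmm <- function(y, x, subject, sampler, seed, random_slope = TRUE) {
  subjects <- sort(unique(subject))
  J <- length(subjects)
  data <- list(y = y, x = x, s = match(subject, subjects), N = length(y), J = J)
  # block samplers for conjugate normal sub-graphs
  try(rjags::load.module("glm", quiet = TRUE), silent = TRUE)
  inits <- lapply(seq_len(sampler$chains), function(ch) {
    ini <- list(b0 = 0, b1 = 0, sigma = 0.5, tau_u1 = 0.1,
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = subseed(seed, ch))
    if (random_slope) {
      ini$tau_u2 <- 0.1
      ini$rho_raw <- 0.5
    }
    ini
  })
  model <- rjags::jags.model(textConnection(jags_lmm_string(random_slope)),
                             data = data, inits = inits,
                             n.chains = sampler$chains,
                             n.adapt = sampler$adapt, quiet = TRUE)
  stats::update(model, n.iter = sampler$warmup, progress.bar = "none")
  monitors <- c("b0", "b1", "sigma", "tau_u1", "u",
                if (random_slope) c("tau_u2", "rho"))
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = sampler$draws, progress.bar = "none")
  core <- c("b0", "b1", "sigma")
  rhat <- coda::gelman.diag(samp[, core, drop = FALSE], autoburnin = FALSE,
                            multivariate = FALSE)$psrf[, 1]
  ess <- coda::effectiveSize(samp[, core, drop = FALSE])
  mat <- as.matrix(samp)
  u0 <- mat[, sprintf("u[%d,1]", seq_len(J)), drop = FALSE]
  u1 <- if (random_slope) {
    mat[, sprintf("u[%d,2]", seq_len(J)), drop = FALSE]
  } else {
    matrix(0, nrow(mat), J)
  }
  list(b0 = mat[, "b0"], b1 = mat[, "b1"], sigma = mat[, "sigma"],
       tau_u1 = mat[, "tau_u1"],
       tau_u2 = if (random_slope) mat[, "tau_u2"] else rep(0, nrow(mat)),
       rho = if (random_slope) mat[, "rho"] else rep(0, nrow(mat)),
       u0 = u0, u1 = u1, subjects = subjects,
       rhat = rhat, ess = ess,
       converged = all(rhat < 1.01, na.rm = TRUE))
}

#' Fit the calibration model (practical vs criterion velocity)
#'
#' Bayesian linear mixed model regressing each repetition's practical-device
#' mean velocity on the criterion mean velocity, with correlated random
#' intercepts and slopes per lifter. The group-level intercept and slope
#' quantify fixed and proportional bias (perfect agreement: 0 and 1);
#' [compute_r2()] and [compute_rmse()] derive random error and absolute
#' precision from this fit.
#'
#' @param data A `vbt_paired` data frame (see [match_reps()]), or any data
#'   frame with columns `subject_id`, `criterion_mv`, `practical_mv`.
#' @param sampler A [sampler_spec()].
#' @param seed Integer seed; fits are reproducible given the seed.
#' @param random_slope Include subject-level random slopes (default TRUE).
#' @return An object of class `vbt_calibration` (inherits `vbt_fit`) with
#'   posterior draws of the natural-scale intercept, slope and residual SD,
#'   subject effects, convergence diagnostics (split R-hat, effective sample
#'   size) and the scaling used. Non-convergence (any R-hat >= 1.01) sets
#'   `converged = FALSE` and raises a warning, never silently.
#' @export
fit_calibration <- function(data, sampler = sampler_spec(), seed = 1L,
                            random_slope = TRUE) {
  stop_if_not(all(c("subject_id", "criterion_mv", "practical_mv") %in%
                    names(data)), "need subject_id, criterion_mv, practical_mv")
  data <- data[stats::complete.cases(data[c("subject_id", "criterion_mv",
                                            "practical_mv")]), , drop = FALSE]
  stop_if_not(length(unique(data$subject_id)) >= 2, "need >= 2 subjects")
  stop_if_not(nrow(data) >= 2 * length(unique(data$subject_id)),
              "need >= 2 repetitions per subject on average")
  mx <- mean(data$criterion_mv)
  sx <- stats::sd(data$criterion_mv)
  stop_if_not(sx > 0, "criterion velocities are constant")
  ys <- (data$practical_mv - mx) / sx
  xs <- (data$criterion_mv - mx) / sx
  res <- run_jags_lmm(ys, xs, data$subject_id, sampler, seed, random_slope)
  # back-transform: slope is scale-free (x and y share the criterion scale);
  # intercept = mx + sx*b0 - slope*mx; residual SD scales by sx
  draws <- data.frame(
    intercept = mx + sx * res$b0 - res$b1 * mx,
    slope = res$b1,
    sigma = sx * res$sigma
  )
  out <- structure(list(
    draws = draws, std = res, data = data,
    scaling = c(mx = mx, sx = sx),
    diagnostics = list(rhat = res$rhat, ess = res$ess,
                       converged = res$converged),
    sampler = sampler, seed = seed, random_slope = random_slope,
    device_id = attr(data, "device_id"), call = match.call()
  ), class = c("vbt_calibration", "vbt_fit"))
  if (!res$converged) {
    warning("calibration model did not converge (max R-hat = ",
            signif(max(res$rhat), 4), ")")
  }
  out
}

#' Fit the mean-bias model (velocity vs measurement source)
#'
#' Bayesian linear mixed model for each repetition's mean velocity as a
#' function of source, a 0/1 dummy for criterion vs practical device, with
#' correlated random intercepts and source effects per lifter. The source
#' effect is the mean velocity difference between device and criterion;
#' dividing it by a reference SD gives the standardized mean bias
#' ([compute_smb()]).
#'
#' @inheritParams fit_calibration
#' @return An object of class `vbt_meanbias` (inherits `vbt_fit`) with
#'   posterior draws of the natural-scale mean difference `delta` (m/s).
#' @export
fit_mean_bias <- function(data, sampler = sampler_spec(), seed = 1L,
                          random_slope = TRUE) {
  stop_if_not(all(c("subject_id", "criterion_mv", "practical_mv") %in%
                    names(data)), "need subject_id, criterion_mv, practical_mv")
  data <- data[stats::complete.cases(data[c("subject_id", "criterion_mv",
                                            "practical_mv")]), , drop = FALSE]
  stop_if_not(length(unique(data$subject_id)) >= 2, "need >= 2 subjects")
  mx <- mean(data$criterion_mv)
  sx <- stats::sd(data$criterion_mv)
  stop_if_not(sx > 0, "criterion velocities are constant")
  # long form: every repetition contributes a criterion and a practical row
  y <- c(data$criterion_mv, data$practical_mv)
  src <- rep(c(0, 1), each = nrow(data))
  subject <- rep(data$subject_id, 2)
  res <- run_jags_lmm((y - mx) / sx, src, subject, sampler, seed, random_slope)
  draws <- data.frame(
    gamma0 = mx + sx * res$b0,
    delta = sx * res$b1,
    sigma = sx * res$sigma
  )
  out <- structure(list(
    draws = draws, std = res, data = data,
    scaling = c(mx = mx, sx = sx),
    diagnostics = list(rhat = res$rhat, ess = res$ess,
                       converged = res$converged),
    sampler = sampler, seed = seed, random_slope = random_slope,
    device_id = attr(data, "device_id"), call = match.call()
  ), class = c("vbt_meanbias", "vbt_fit"))
  if (!res$converged) {
    warning("mean-bias model did not converge (max R-hat = ",
            signif(max(res$rhat), 4), ")")
  }
  out
}

# --- methods ----------------------------------------------------------------

#' @export
print.vbt_fit <- function(x, ...) {
  kind <- if (inherits(x, "vbt_calibration")) "calibration" else "mean-bias"
  cat(sprintf("Bayesian %s mixed model (%d draws, %d chains)\n",
              kind, nrow(x$draws), x$sampler$chains))
  if (!is.null(x$device_id)) cat("device:", x$device_id, "\n")
  print(vapply(x$draws, mean, numeric(1)), digits = 4)
  if (!x$diagnostics$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

#' @export
coef.vbt_calibration <- function(object, ...) {
  c(intercept = mean(object$draws$intercept), slope = mean(object$draws$slope))
}

#' @export
coef.vbt_meanbias <- function(object, ...) {
  c(mean_difference = mean(object$draws$delta))
}

#' @export
summary.vbt_fit <- function(object, mass = 0.95, ...) {
  stats_df <- do.call(rbind, lapply(names(object$draws), function(nm) {
    h <- hdi(object$draws[[nm]], mass)
    data.frame(statistic = nm, mean = mean(object$draws[[nm]]),
               hdi_lower = h[["lower"]], hdi_upper = h[["upper"]])
  }))
  stats_df$rhat_max <- max(object$diagnostics$rhat)
  stats_df$ess_min <- min(object$diagnostics$ess)
  stats_df$converged <- object$diagnostics$converged
  stats_df
}

# Conditional expectation per posterior draw on the standardized scale.
draw_linpred <- function(fit, xs, subject) {
  idx <- match(subject, fit$std$subjects)
  stop_if_not(!anyNA(idx), "unknown subject in prediction data")
  b0 <- fit$std$b0
  b1 <- fit$std$b1
  u0 <- fit$std$u0[, idx, drop = FALSE]
  u1 <- fit$std$u1[, idx, drop = FALSE]
  (b0 + u0) + sweep(u1, 2, xs, `*`) + outer(b1, xs)
}

#' @export
predict.vbt_calibration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  mx <- object$scaling[["mx"]]
  sx <- object$scaling[["sx"]]
  xs <- (newdata$criterion_mv - mx) / sx
  lp <- draw_linpred(object, xs, newdata$subject_id)
  unname(mx + sx * colMeans(lp))
}

#' @export
fitted.vbt_calibration <- function(object, ...) predict(object)

#' @export
residuals.vbt_calibration <- function(object, ...) {
  object$data$practical_mv - fitted(object)
}

#' @export
plot.vbt_calibration <- function(x, ...) {
  d <- x$data
  graphics::plot(d$criterion_mv, d$practical_mv,
                 xlab = "criterion mean velocity (m/s)",
                 ylab = "practical mean velocity (m/s)",
                 pch = 16, col = "#00000055", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(mean(x$draws$intercept), mean(x$draws$slope), col = 2)
  invisible(x)
}
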