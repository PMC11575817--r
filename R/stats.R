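# Posterior validity statistics derived from the mixed-model fits.

#' Posterior summary container
#'
#' @param draws Numeric vector of posterior draws of a statistic.
#' @param statistic Statistic name.
#' @param mass HDI mass.
#' @param rhat,ess Diagnostics inherited from the parent fit.
#' @param flagged TRUE when the parent fit failed its convergence gate;
#'   summaries from flagged fits are reported but marked.
#' @return A list of class `vbt_posterior` with elements `statistic`, `mean`,
#'   `hdi_lower`, `hdi_upper`, `draws`, `rhat`, `ess`, `flagged`.
#' @export
posterior_summary <- function(draws, statistic, mass = 0.95,
                              rhat = NA_real_, ess = NA_real_,
                              flagged = FALSE) {
  h <- hdi(draws, mass)
  structure(list(statistic = statistic,
                 mean = mean(draws),
                 hdi_lower = h[["lower"]],
                 hdi_upper = h[["upper"]],
                 draws = draws,
                 rhat = rhat, ess = ess, flagged = flagged),
            class = "vbt_posterior")
}

#' @export
print.vbt_posterior <- function(x, ...) {
  cat(sprintf("%s: %.4g [%.4g, %.4g] (95%% HDI)%s\n", x$statistic, x$mean,
              x$hdi_lower, x$hdi_upper,
              if (isTRUE(x$flagged)) " [non-converged fit]" else ""))
  invisible(x)
}

fit_gate <- function(fit) {
  list(rhat = max(fit$diagnostics$rhat), ess = min(fit$diagnostics$ess),
       flagged = !fit$diagnostics$converged)
}

#' Standardized mean bias
#'
#' Per-draw standardized mean bias: the mean-bias model's source effect
#' (device minus criterion, m/s) divided by a reference SD, by default the SD
#' of the criterion mean velocities in the analyzed dataset, making the bias
#' unit-free and criterion-anchored.
#'
#' @param fit A `vbt_meanbias` fit.
#' @param scale_sd Standardizing SD in m/s (> 0).
#' @param mass HDI mass.
#' @return A [posterior_summary()] of the SMB.
#' @export
compute_smb <- function(fit, scale_sd = NULL, mass = 0.95) {
  stopifnot(inherits(fit, "vbt_meanbias"))
  scale_sd <- scale_sd %||% fit$scaling[["sx"]]
  stop_if_not(is.numeric(scale_sd) && scale_sd > 0, "scale_sd must be > 0")
  g <- fit_gate(fit)
  posterior_summary(fit$draws$delta / scale_sd, "smb", mass,
                    rhat = g$rhat, ess = g$ess, flagged = g$flagged)
}

#' Root mean squared error from posterior predictions
#'
#' Per-draw RMSE of the calibration model's conditional expectations (fixed
#' plus subject effects; no residual draw added) against the observed
#' practical velocities, representing absolute precision in m/s.
#'
#' @param fit A `vbt_calibration` fit.
#' @param data Paired dataset; defaults to the fit's own data.
#' @param ppc_noise Add a residual-variance term to the predictive spread
#'   (`"off"`, the default, uses conditional means only).
#' @param mass HDI mass.
#' @return A [posterior_summary()] of the RMSE.
#' @export
compute_rmse <- function(fit, data = fit$data, ppc_noise = c("off", "on"),
                         mass = 0.95) {
  stopifnot(inherits(fit, "vbt_calibration"))
  ppc_noise <- match.arg(ppc_noise)
  sx <- fit$scaling[["sx"]]
  mx <- fit$scaling[["mx"]]
  xs <- (data$criterion_mv - mx) / sx
  ys <- (data$practical_mv - mx) / sx
  lp <- draw_linpred(fit, xs, data$subject_id)
  sq <- rowMeans((lp - matrix(ys, nrow(lp), length(ys), byrow = TRUE))^2)
  if (ppc_noise == "on") sq <- sq + fit$std$sigma^2
  g <- fit_gate(fit)
  posterior_summary(sx * sqrt(sq), "rmse", mass,
                    rhat = g$rhat, ess = g$ess, flagged = g$flagged)
}

#' Bayesian R-squared
#'
#' Per-draw R2 = Var(fitted) / (Var(fitted) + Var(residual)) over the
#' dataset, with fitted values the conditional expectations of the
#' calibration model; a standardized indicator of random error.
#'
#' @inheritParams compute_rmse
#' @return A [posterior_summary()] of R2.
#' @export
compute_r2 <- function(fit, data = fit$data, mass = 0.95) {
  stopifnot(inherits(fit, "vbt_calibration"))
  sx <- fit$scaling[["sx"]]
  mx <- fit$scaling[["mx"]]
  xs <- (data$criterion_mv - mx) / sx
  ys <- (data$practical_mv - mx) / sx
  lp <- draw_linpred(fit, xs, data$subject_id)
  res <- lp - matrix(ys, nrow(lp), length(ys), byrow = TRUE)
  var_fit <- apply(lp, 1, stats::var)
  var_res <- apply(res, 1, stats::var)
  g <- fit_gate(fit)
  posterior_summary(var_fit / (var_fit + var_res), "r2", mass,
                    rhat = g$rhat, ess = g$ess, flagged = g$flagged)
}

#' Posterior intercept and slope summaries of a calibration fit
#'
#' @param fit A `vbt_calibration` fit.
#' @param mass HDI mass.
#' @return A named list of [posterior_summary()] objects for `intercept` and
#'   `slope`.
#' @export
compute_bias_lines <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "vbt_calibration"))
  g <- fit_gate(fit)
  list(
    intercept = posterior_summary(fit$draws$intercept, "intercept", mass,
                                  rhat = g$rhat, ess = g$ess,
                                  flagged = g$flagged),
    slope = posterior_summary(fit$draws$slope, "slope", mass,
                              rhat = g$rhat, ess = g$ess, flagged = g$flagged)
  )
}
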