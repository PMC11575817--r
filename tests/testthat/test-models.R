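# Mixed-model fits: parameter recovery against known generative truth and
# independent least-squares oracles. Reduced sampler settings (see helper)
# keep each fit at a few seconds.

test_that("an identity device yields a near-perfect calibration fit", {
  paired <- make_paired(alpha = 0, beta = 1, sigma = 0.001, seed = 21)
  fit <- fit_calibration(paired, sampler = quick_sampler(), seed = 101)
  expect_true(fit$diagnostics$converged)
  expect_gte(nrow(fit$draws), 1000)
  co <- coef(fit)
  expect_gt(co[["slope"]], 0.99)
  expect_lt(co[["slope"]], 1.01)
  expect_lt(abs(co[["intercept"]]), 0.005)
  expect_lt(compute_rmse(fit)$mean, 0.003)
  expect_gt(compute_r2(fit)$mean, 0.999)
})

test_that("a constant offset is recovered as the mean difference and SMB", {
  paired <- make_paired(alpha = 0.05, beta = 1, sigma = 0.001, seed = 22)
  fit2 <- fit_mean_bias(paired, sampler = quick_sampler(), seed = 102)
  expect_true(fit2$diagnostics$converged)
  delta <- mean(fit2$draws$delta)
  expect_gt(delta, 0.045)
  expect_lt(delta, 0.055)
  smb <- compute_smb(fit2)
  # SMB * scale_sd reproduces delta draw by draw
  expect_equal(smb$draws * fit2$scaling[["sx"]], fit2$draws$delta,
               tolerance = 1e-12)
  # an offset of 0.3 criterion SDs lands near SMB = 0.3
  sx <- sd(paired$criterion_mv)
  shifted <- paired
  shifted$practical_mv <- shifted$criterion_mv + 0.3 * sx
  fit3 <- fit_mean_bias(shifted, sampler = quick_sampler(), seed = 103)
  smb3 <- compute_smb(fit3)
  expect_gt(smb3$mean, 0.2)
  expect_lt(smb3$mean, 0.4)
})

test_that("fixed and proportional bias are recovered; slope matches OLS", {
  paired <- make_paired(alpha = 0.05, beta = 0.90, sigma = 0.03, seed = 23)
  fit <- fit_calibration(paired, sampler = quick_sampler(), seed = 104)
  expect_true(fit$diagnostics$converged)
  expect_lt(abs(mean(fit$draws$intercept) - 0.05), 0.02)
  expect_lt(abs(mean(fit$draws$slope) - 0.90), 0.03)
  # with no subject random effects in the truth, the pooled OLS slope is an
  # independent oracle for the posterior mean
  ols <- coef(lm(practical_mv ~ criterion_mv, data = paired))
  expect_lt(abs(mean(fit$draws$slope) - ols[[2]]),
            3 * sd(fit$draws$slope))
  # predictions and residuals are consistent
  expect_equal(fitted(fit) + residuals(fit), paired$practical_mv)
  expect_lt(sd(residuals(fit)), 0.05)
})

test_that("back-transformed standardized fits match natural-scale fits", {
  paired <- make_paired(alpha = 0.03, beta = 0.95, sigma = 0.02, seed = 24)
  fit <- fit_calibration(paired, sampler = quick_sampler(), seed = 105)
  nat <- vbtvalid:::run_jags_lmm(paired$practical_mv, paired$criterion_mv,
                                 paired$subject_id, quick_sampler(),
                                 seed = 106)
  expect_lt(abs(mean(fit$draws$intercept) - mean(nat$b0)), 0.02)
  expect_lt(abs(mean(fit$draws$slope) - mean(nat$b1)), 0.03)
  expect_lt(abs(mean(fit$draws$sigma) - mean(nat$sigma)), 0.01)
})

test_that("RMSE tracks the residual SD and R2 falls as noise grows", {
  sigmas <- c(0.01, 0.025, 0.05, 0.09)
  fits <- lapply(seq_along(sigmas), function(i) {
    paired <- make_paired(alpha = 0, beta = 1, sigma = sigmas[i], seed = 30)
    fit_calibration(paired, sampler = quick_sampler(), seed = 110 + i)
  })
  rmse <- vapply(fits, function(f) compute_rmse(f)$mean, numeric(1))
  r2 <- vapply(fits, function(f) compute_r2(f)$mean, numeric(1))
  # for a correctly specified model the posterior RMSE approaches sigma
  expect_gt(rmse[3], 0.045)
  expect_lt(rmse[3], 0.055)
  # doubling sigma doubles the RMSE within 10%
  expect_gt(rmse[3] / rmse[2], 1.8)
  expect_lt(rmse[3] / rmse[2], 2.2)
  # monotone decline of R2 with noise
  expect_true(all(diff(r2) < 0))
  # variance-ratio oracle at sigma = 0.05
  paired <- make_paired(alpha = 0, beta = 1, sigma = 0.05, seed = 30)
  expected_r2 <- var(paired$criterion_mv) /
    (var(paired$criterion_mv) + 0.05^2)
  expect_equal(r2[3], expected_r2, tolerance = 0.015)
})

test_that("posterior summaries carry diagnostics and fits expose them", {
  paired <- make_paired(sigma = 0.02, seed = 25)
  fit <- fit_calibration(paired, sampler = quick_sampler(), seed = 107)
  s <- summary(fit)
  expect_true(all(c("rhat_max", "ess_min", "converged") %in% names(s)))
  expect_true(all(s$hdi_lower <= s$mean & s$mean <= s$hdi_upper))
  r2 <- compute_r2(fit)
  expect_false(is.na(r2$rhat))
  expect_false(is.na(r2$ess))
  expect_false(r2$flagged)
})

test_that("SMB arithmetic is exact for degenerate draws", {
  fake <- structure(list(
    draws = data.frame(gamma0 = rep(0.4, 200), delta = rep(0.034, 200),
                       sigma = rep(0.01, 200)),
    scaling = c(mx = 0.4, sx = 0.17),
    diagnostics = list(rhat = c(b0 = 1), ess = c(b0 = 1e4), converged = TRUE)
  ), class = c("vbt_meanbias", "vbt_fit"))
  smb <- compute_smb(fake, scale_sd = 0.17)
  expect_equal(smb$mean, 0.2)
  expect_equal(unname(c(smb$hdi_lower, smb$hdi_upper)), c(0.2, 0.2))
  expect_error(compute_smb(fake, scale_sd = 0), "scale_sd")
  zero <- fake
  zero$draws$delta <- 0
  expect_equal(compute_smb(zero)$mean, 0)
})
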