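test_that("ROPE construction follows the extreme-HDI-limit rule per statistic", {
  # two-sided statistic: symmetric about the perfect value, half-width =
  # distance of the farther 95% HDI limit (e.g. SMB HDI [0.04, 0.38] -> ROPE
  # [-0.38, 0.38])
  smb_draws <- with_test_seed(1, rnorm(1e5, 0.21, 0.0867))
  rope <- build_rope(smb_draws, "smb")
  h <- hdi(smb_draws)
  expect_equal(rope$high, max(abs(h)))
  expect_equal(rope$low, -max(abs(h)))
  expect_equal(rope$high, 0.38, tolerance = 0.01)

  # slope: symmetric about 1
  sl_draws <- with_test_seed(2, rnorm(1e5, 0.99, 0.005))
  rs <- build_rope(sl_draws, "slope")
  half <- max(abs(hdi(sl_draws) - 1))
  expect_equal(c(rs$low, rs$high), c(1 - half, 1 + half))

  # R2 is bounded above: [extreme lower limit, 1]
  r2_draws <- with_test_seed(3, 0.9983 + 0.0001 * rnorm(1e5))
  rr <- build_rope(r2_draws, "r2")
  expect_equal(rr$high, 1)
  expect_equal(rr$low, hdi(r2_draws)[["lower"]])

  # RMSE is bounded below: [0, extreme upper limit]
  rm_draws <- with_test_seed(4, abs(rnorm(1e5, 0.02, 0.003)))
  rrm <- build_rope(rm_draws, "rmse")
  expect_equal(rrm$low, 0)
  expect_equal(rrm$high, hdi(rm_draws)[["upper"]])

  # degenerate reference: zero-width region at the perfect value
  expect_equal(unlist(build_rope(rep(0, 200), "smb")[c("low", "high")]),
               c(low = 0, high = 0))
})

test_that("ROPE membership probability is the inclusive draw fraction", {
  u <- with_test_seed(5, runif(1e5))
  rope <- structure(list(statistic = "smb", low = 0, high = 0.25,
                         perfect = 0), class = "vbt_rope")
  expect_lt(abs(rope_probability(u, rope) - 0.25), 0.01)
  inside <- runif(200, 0.05, 0.2)
  expect_equal(rope_probability(inside, rope), 1)
  expect_error(rope_probability(runif(10), rope), "100 draws")
})

test_that("direction probabilities match the normal CDF oracle", {
  z <- with_test_seed(6, rnorm(1e5))
  expect_equal(direction_probability(z, 0, "below"), 0.5, tolerance = 0.01)
  shifted <- with_test_seed(7, rnorm(1e5, -0.5, 0.18))
  expect_equal(direction_probability(shifted, 0, "below"),
               pnorm(0.5 / 0.18), tolerance = 0.005)
  expect_equal(direction_probability(rep(-1, 200), 0, "below"), 1)
})

test_that("classification reproduces the 95% decision rule", {
  # the boundary case: 94.5% membership misses the threshold for a clear call
  expect_equal(classify_equivalence(0.945), "unclear")
  expect_equal(classify_equivalence(0.95), "likely_equivalent")
  expect_equal(classify_equivalence(1.0), "likely_equivalent")
  expect_equal(classify_equivalence(0.01, p_below_low = 0.99),
               "likely_different")
  expect_equal(classify_equivalence(0.04), "likely_different")
  # clear direction outside the region dominates an otherwise unclear p
  expect_equal(classify_equivalence(0.5, p_above_high = 0.96),
               "likely_different")
  expect_equal(classify_equivalence(0.5), "unclear")
  expect_error(classify_equivalence(1.2), "\\[0, 1\\]")
})

test_that("classification is total and widening a ROPE never lowers membership", {
  labels <- c("likely_equivalent", "likely_different", "unclear")
  cases <- with_test_seed(8, data.frame(p = runif(200), b = runif(200),
                                        a = runif(200)))
  for (i in seq_len(nrow(cases))) {
    out <- classify_equivalence(cases$p[i], cases$b[i], cases$a[i])
    expect_true(out %in% labels)
  }
  draws <- with_test_seed(9, rnorm(5000, 0.1, 0.2))
  widths <- seq(0.05, 0.8, by = 0.05)
  probs <- vapply(widths, function(w) {
    rope <- structure(list(statistic = "smb", low = -w, high = w,
                           perfect = 0), class = "vbt_rope")
    rope_probability(draws, rope)
  }, numeric(1))
  expect_true(all(diff(probs) >= 0))
})
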