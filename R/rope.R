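# Reference-device-anchored region of practical equivalence.

PERFECT_VALUES <- c(intercept = 0, slope = 1, r2 = 1, rmse = 0, smb = 0)

#' Build a region of practical equivalence from a reference posterior
#'
#' The ROPE for each statistic is anchored at the value indicating a perfect
#' match (intercept 0, slope 1, R2 1, RMSE 0, SMB 0) and sized by the
#' reference device's posterior: the 95% HDI limit farther from the perfect
#' value sets the region. For two-sided statistics (intercept, slope, SMB)
#' the region is symmetric about the perfect value with half-width
#' |extreme limit - perfect value|; R2 is bounded above by 1 so its region is
#' [extreme lower limit, 1]; RMSE is bounded below by 0 so its region is
#' [0, extreme upper limit].
#'
#' @param reference_draws Posterior draws of the statistic for the reference
#'   device, or a `vbt_posterior`.
#' @param statistic One of `"intercept"`, `"slope"`, `"r2"`, `"rmse"`,
#'   `"smb"`.
#' @param mass HDI mass used for the reference interval.
#' @return A list of class `vbt_rope` with elements `statistic`, `low`,
#'   `high`, `perfect`, `reference_hdi`.
#' @export
#' @examples
#' build_rope(rnorm(4000, 0.99, 0.01), "slope")
build_rope <- function(reference_draws, statistic, mass = 0.95) {
  statistic <- match.arg(statistic, names(PERFECT_VALUES))
  if (inherits(reference_draws, "vbt_posterior")) {
    reference_draws <- reference_draws$draws
  }
  perfect <- PERFECT_VALUES[[statistic]]
  h <- hdi(reference_draws, mass)
  if (statistic == "r2") {
    low <- min(h[["lower"]], 1)
    region <- c(low = low, high = 1)
  } else if (statistic == "rmse") {
    region <- c(low = 0, high = max(h[["upper"]], 0))
  } else {
    half <- max(abs(h - perfect))
    region <- c(low = perfect - half, high = perfect + half)
  }
  stop_if_not(region[["low"]] <= perfect && perfect <= region[["high"]],
              "reference interval admits no equivalent values")
  structure(list(statistic = statistic, low = region[["low"]],
                 high = region[["high"]], perfect = perfect,
                 reference_hdi = h),
            class = "vbt_rope")
}

#' Probability that a posterior falls inside a ROPE
#'
#' Fraction of draws inside the region, bounds inclusive.
#'
#' @param draws Posterior draws (>= 100), or a `vbt_posterior`.
#' @param rope A `vbt_rope` from [build_rope()].
#' @return A probability in `[0, 1]`.
#' @export
rope_probability <- function(draws, rope) {
  stopifnot(inherits(rope, "vbt_rope"))
  if (inherits(draws, "vbt_posterior")) draws <- draws$draws
  stop_if_not(length(draws) >= 100, "need at least 100 draws")
  mean(draws >= rope$low & draws <= rope$high)
}

#' Probability of an effect direction
#'
#' Fraction of draws strictly below or above a threshold, e.g.
#' `p(intercept < 0)` relative to the line of identity.
#'
#' @param draws Posterior draws (>= 100), or a `vbt_posterior`.
#' @param threshold Comparison value.
#' @param side `"below"` or `"above"`.
#' @return A probability in `[0, 1]`.
#' @export
direction_probability <- function(draws, threshold, side = c("below", "above")) {
  side <- match.arg(side)
  if (inherits(draws, "vbt_posterior")) draws <- draws$draws
  stop_if_not(length(draws) >= 100, "need at least 100 draws")
  if (side == "below") mean(draws < threshold) else mean(draws > threshold)
}

#' Classify a device posterior against a ROPE
#'
#' A decision is statistically clear only when supported by at least
#' `rule_mass` posterior probability: `likely_equivalent` when
#' `p_in_rope >= rule_mass`; `likely_different` when `p_in_rope <= 1 -
#' rule_mass`, or when the probability of lying on one specific side outside
#' the region reaches `rule_mass` while `p_in_rope < rule_mass`; otherwise
#' `unclear` (e.g. p = 0.945 misses the 0.95 threshold for a clear effect).
#'
#' @param p_in_rope Probability that the statistic falls inside the ROPE.
#' @param p_below_low,p_above_high Probabilities of lying outside the region
#'   on each side.
#' @param rule_mass Decision threshold, default 0.95.
#' @return One of `"likely_equivalent"`, `"likely_different"`, `"unclear"`.
#' @export
#' @examples
#' classify_equivalence(0.945)   # "unclear"
#' classify_equivalence(1.0)     # "likely_equivalent"
classify_equivalence <- function(p_in_rope, p_below_low = 0,
                                 p_above_high = 0, rule_mass = 0.95) {
  stop_if_not(all(c(p_in_rope, p_below_low, p_above_high) >= 0 &
                    c(p_in_rope, p_below_low, p_above_high) <= 1),
              "probabilities must lie in [0, 1]")
  if (p_in_rope >= rule_mass) return("likely_equivalent")
  if (p_in_rope <= 1 - rule_mass) return("likely_different")
  if (max(p_below_low, p_above_high) >= rule_mass) return("likely_different")
  "unclear"
}

#' @export
print.vbt_rope <- function(x, ...) {
  cat(sprintf("ROPE for %s: [%.4g, %.4g] (perfect = %g)\n",
              x$statistic, x$low, x$high, x$perfect))
  invisible(x)
}
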