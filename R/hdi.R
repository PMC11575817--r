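#' Highest density interval of a posterior sample
#'
#' Shortest contiguous interval containing at least `mass` of the draws:
#' among all windows of `ceiling(mass * n)` consecutive sorted draws, the one
#' with the smallest width (earliest such window on ties).
#'
#' @param draws Numeric vector of posterior draws (>= 100).
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' hdi(rnorm(10000))
hdi <- function(draws, mass = 0.95) {
  stop_if_not(is.numeric(draws) && length(draws) >= 100,
              "need at least 100 draws")
  stop_if_not(mass > 0 && mass < 1, "mass must lie in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}
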