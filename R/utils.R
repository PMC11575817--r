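# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library calls never disturb a caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps values well below 2^31.
subseed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Round to the nearest multiple of `increment`, ties rounding half up
# (plate loading convention: 86.25 kg -> 87.5 kg at 2.5 kg increments).
round_to_increment <- function(x, increment) {
  stop_if_not(is.numeric(increment) && increment > 0,
              "rounding increment must be > 0")
  floor(x / increment + 0.5) * increment
}

EXERCISES <- c("squat", "bench", "deadlift")

match_exercise <- function(exercise) {
  match.arg(exercise, EXERCISES)
}
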