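REP_COLS <- c("subject_id", "exercise", "load_pct", "set_index", "rep_index",
              "device_id", "mean_velocity", "status")

set_key <- function(df) {
  paste(df$subject_id, df$exercise, df$load_pct, df$set_index, sep = "\r")
}

validate_observations <- function(df, label = "observations") {
  stop_if_not(all(REP_COLS %in% names(df)),
              sprintf("%s must have columns: %s", label,
                      paste(REP_COLS, collapse = ", ")))
  bad <- which((df$status == "ok") != !is.na(df$mean_velocity))
  if (length(bad)) {
    stop(sprintf("%s: mean_velocity must be present iff status is 'ok' (row %d)",
                 label, bad[1]), call. = FALSE)
  }
  neg <- which(df$status == "ok" & df$mean_velocity <= 0)
  if (length(neg)) {
    stop(sprintf("%s: mean_velocity must be positive (row %d)", label, neg[1]),
         call. = FALSE)
  }
  key <- paste(set_key(df), df$rep_index, df$device_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("%s: duplicate (subject, exercise, load, set, rep, device) key",
                 label), call. = FALSE)
  }
  invisible(df)
}

#' Pair criterion and practical-device repetitions
#'
#' Matches repetitions within each (subject, exercise, load, set) cell by
#' order: the k-th criterion `"ok"` repetition pairs with the k-th practical
#' `"ok"` repetition. Criterion repetitions without a practical partner are
#' counted as missed; practical observations flagged `"ghost"` are excluded
#' from pairing and counted separately. With single-repetition sets (the
#' usual loading-ladder protocol) order-based matching is exact; multi-rep
#' sets are supported but rely on detection order.
#'
#' @param criterion,practical Repetition-observation data frames (see
#'   [simulate_device()] for the schema).
#' @return A data frame of class `vbt_paired` with columns `subject_id`,
#'   `exercise`, `load_pct`, `set_index`, `criterion_mv`, `practical_mv`, and
#'   attributes `device_id`, `n_paired`, `n_missed`, `n_ghost`.
#' @export
match_reps <- function(criterion, practical) {
  validate_observations(criterion, "criterion")
  validate_observations(practical, "practical")
  device <- unique(practical$device_id)
  stop_if_not(length(device) == 1, "practical stream must hold one device")
  crit_ok <- criterion[criterion$status == "ok", , drop = FALSE]
  prac_ok <- practical[practical$status == "ok", , drop = FALSE]
  n_ghost <- sum(practical$status == "ghost")
  ord <- function(d) d[order(d$subject_id, d$exercise, d$load_pct,
                             d$set_index, d$rep_index), , drop = FALSE]
  crit_ok <- ord(crit_ok)
  prac_ok <- ord(prac_ok)
  ck <- set_key(crit_ok)
  pk <- set_key(prac_ok)
  crit_ok$.pos <- stats::ave(seq_along(ck), ck, FUN = seq_along)
  prac_ok$.pos <- stats::ave(seq_along(pk), pk, FUN = seq_along)
  m <- match(paste(pk, prac_ok$.pos, sep = "\r"),
             paste(ck, crit_ok$.pos, sep = "\r"))
  paired_idx <- which(!is.na(m))
  # practical "ok" reps beyond the criterion count in a set were never
  # performed: count them as ghosts (rule-based ghost detection for tables
  # without an explicit ghost flag)
  n_ghost <- n_ghost + sum(is.na(m))
  out <- data.frame(
    subject_id = crit_ok$subject_id[m[paired_idx]],
    exercise = crit_ok$exercise[m[paired_idx]],
    load_pct = crit_ok$load_pct[m[paired_idx]],
    set_index = crit_ok$set_index[m[paired_idx]],
    criterion_mv = crit_ok$mean_velocity[m[paired_idx]],
    practical_mv = prac_ok$mean_velocity[paired_idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$subject_id, out$exercise, out$load_pct, out$set_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("vbt_paired", "data.frame"),
            device_id = device,
            n_paired = nrow(out),
            n_missed = nrow(crit_ok) - nrow(out),
            n_ghost = n_ghost)
}

#' Missed-repetition rate of a paired dataset
#'
#' Fraction of performed (criterion) repetitions that the practical device
#' failed to identify: `n_missed / (n_paired + n_missed)`.
#'
#' @param paired A `vbt_paired` data frame from [match_reps()].
#' @return A single fraction in `[0, 1]`.
#' @export
missed_rate <- function(paired) {
  stopifnot(inherits(paired, "vbt_paired"))
  n <- attr(paired, "n_paired") + attr(paired, "n_missed")
  stop_if_not(n > 0, "empty paired dataset")
  attr(paired, "n_missed") / n
}

#' Descriptive statistics of recorded mean velocities
#'
#' @param observations Repetition-observation data frame; only `"ok"` rows
#'   enter the summary.
#' @param velocities Alternatively, a plain numeric vector of velocities.
#' @return Named list: `n`, `mean`, `sd` (n-1 denominator; 0 with attribute
#'   `sd_undefined = TRUE` when n = 1), `min`, `max`.
#' @export
summarize_velocities <- function(observations = NULL, velocities = NULL) {
  v <- if (!is.null(velocities)) {
    velocities
  } else {
    observations$mean_velocity[observations$status == "ok"]
  }
  stop_if_not(length(v) >= 1, "need at least one recorded repetition")
  out <- list(n = length(v), mean = mean(v),
              sd = if (length(v) > 1) stats::sd(v) else 0,
              min = min(v), max = max(v))
  if (length(v) == 1) attr(out$sd, "sd_undefined") <- TRUE
  out
}

# --- delimited-text interfaces ---------------------------------------------

#' Write / read a trajectory file
#'
#' Trajectories are exchanged as comma-delimited text with a header row and
#' columns `time_s`, `x_m`, `y_m`, `z_m` (z vertical), the conventional text
#' export of processed motion-capture data.
#'
#' @param traj A `vbt_trajectory`.
#' @param path File path; the conventional pattern is
#'   `{subject}_{exercise}_{load_pct}.csv`.
#' @return `read_trajectory()` returns a `vbt_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[c("time_s", "x_m", "y_m", "z_m")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param sampling_rate Optional sampling rate override; inferred from the
#'   time stamps when omitted.
#' @export
read_trajectory <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "z_m") %in% names(df)) && ncol(df) == 2) {
    names(df) <- c("time_s", "z_m")  # minimal two-column form
  }
  stop_if_not(all(c("time_s", "z_m") %in% names(df)),
              "trajectory file needs time_s and z_m columns")
  if (is.null(df$x_m)) df$x_m <- 0
  if (is.null(df$y_m)) df$y_m <- 0
  stop_if_not(!anyNA(df[c("time_s", "x_m", "y_m", "z_m")]),
              "trajectory contains missing coordinates")
  dts <- diff(df$time_s)
  stop_if_not(all(dts > 0), "time stamps must be strictly increasing")
  stop_if_not(max(dts) - min(dts) < 1e-6, "sampling must be uniform")
  structure(df[c("time_s", "x_m", "y_m", "z_m")],
            class = c("vbt_trajectory", "data.frame"),
            sampling_rate = sampling_rate %||% (1 / stats::median(dts)))
}

#' Write / read a repetition-observation table
#'
#' Comma-delimited text with columns `subject_id`, `exercise`, `load_pct`,
#' `set_index`, `rep_index`, `device_id`, `mean_velocity_mps` (empty when the
#' repetition was missed or ghost), `status` (`ok`/`missed`/`ghost`).
#'
#' @param observations Repetition-observation data frame.
#' @param path File path.
#' @return `read_rep_table()` returns a validated observation data frame.
#' @export
write_rep_table <- function(observations, path) {
  validate_observations(observations)
  out <- observations[REP_COLS]
  names(out)[names(out) == "mean_velocity"] <- "mean_velocity_mps"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_rep_table
#' @export
read_rep_table <- function(path) {
  df <- utils::read.csv(path, na.strings = "",
                        colClasses = c(subject_id = "character",
                                       exercise = "character",
                                       device_id = "character",
                                       status = "character"))
  names(df)[names(df) == "mean_velocity_mps"] <- "mean_velocity"
  if (!"mean_velocity" %in% names(df)) df$mean_velocity <- NA_real_
  df$mean_velocity <- as.numeric(df$mean_velocity)
  validate_observations(df, label = basename(path))
  df
}
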