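# End-to-end study orchestration: simulate -> detect -> match -> fit -> ROPE.

#' Default device profiles for a simulated validity study
#'
#' Four archetypes spanning the error structures seen in practice: a
#' low-error linear transducer used as the practical reference, a
#' near-equivalent app, an app with marked proportional bias and occasional
#' missed/ghost repetitions, and a noisy app with a high missed-repetition
#' rate.
#'
#' @return Named list of [device_profile()] objects.
#' @export
default_devices <- function() {
  list(
    lt_ref = device_profile("lt_ref", alpha = 0.005, beta = 1.00,
                            sigma = 0.015, re_sd = c(0.004, 0.01),
                            re_cor = 0.2),
    app_good = device_profile("app_good", alpha = 0.0, beta = 1.00,
                              sigma = 0.02, re_sd = c(0.004, 0.01),
                              re_cor = 0.2),
    app_biased = device_profile("app_biased", alpha = 0.05, beta = 0.85,
                                sigma = 0.05, re_sd = c(0.01, 0.03),
                                re_cor = 0.2, miss_prob = 0.07,
                                ghost_prob = 0.02),
    app_noisy = device_profile("app_noisy", alpha = 0.02, beta = 0.95,
                               sigma = 0.10, re_sd = c(0.01, 0.03),
                               re_cor = 0.2, miss_prob = 0.10)
  )
}

#' Study configuration
#'
#' @param seed Global seed; every stochastic stage derives its stream from it.
#' @param n_subjects Cohort size.
#' @param protocol A [protocol_spec()].
#' @param trajectories Named list of [trajectory_config()]s per exercise.
#' @param devices Named list of [device_profile()]s.
#' @param criterion_id Label of the criterion system.
#' @param reference_id Device anchoring the ROPE; must name one of `devices`.
#' @param sampler A [sampler_spec()].
#' @param rope_mass Posterior mass for HDIs and the decision rule.
#' @param statistics Validity statistics to compute.
#' @return A list of class `vbt_config`.
#' @export
study_config <- function(seed = 1L,
                         n_subjects = 20L,
                         protocol = protocol_spec(),
                         trajectories = NULL,
                         devices = default_devices(),
                         criterion_id = "vicon",
                         reference_id = "lt_ref",
                         sampler = sampler_spec(),
                         rope_mass = 0.95,
                         statistics = c("intercept", "slope", "r2", "rmse",
                                        "smb")) {
  trajectories <- trajectories %||%
    lapply(stats::setNames(EXERCISES, EXERCISES), trajectory_config)
  stop_if_not(all(vapply(devices, inherits, logical(1), "vbt_device")),
              "devices must be device_profile() objects")
  ids <- vapply(devices, `[[`, character(1), "device_id")
  names(devices) <- ids
  stop_if_not(reference_id %in% ids, "reference_id must name one device")
  statistics <- match.arg(statistics, several.ok = TRUE)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 protocol = protocol, trajectories = trajectories,
                 devices = devices, criterion_id = criterion_id,
                 reference_id = reference_id, sampler = sampler,
                 rope_mass = rope_mass, statistics = statistics),
            class = "vbt_config")
}

# Simulate trajectories for the whole cohort and run the criterion pipeline.
# Returns criterion observations plus the noiseless true mean velocities.
simulate_criterion_stage <- function(config) {
  cohort <- simulate_cohort(config$n_subjects, subseed(config$seed, 1))
  crit <- list()
  truth <- list()
  k <- 0L
  for (ex in names(config$trajectories)) {
    tcfg <- config$trajectories[[ex]]
    for (i in seq_len(nrow(cohort))) {
      fractions <- config$protocol$load_fractions
      for (li in seq_along(fractions)) {
        k <- k + 1L
        tr <- simulate_trajectory(ex, fractions[li], tcfg,
                                  seed = subseed(config$seed, 100L + k))
        attr(tr, "subject_id") <- cohort$subject_id[i]
        attr(tr, "set_index") <- li
        obs <- process_attempt(tr, expected_reps = config$protocol$reps_per_load,
                               device_id = config$criterion_id)
        crit[[k]] <- obs
        truth[[k]] <- data.frame(
          subject_id = cohort$subject_id[i], exercise = ex,
          load_pct = round(100 * fractions[li]), set_index = li,
          rep_index = seq_len(config$protocol$reps_per_load),
          true_mv = attr(tr, "true_mean_velocity"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(cohort = cohort,
       criterion = do.call(rbind, crit),
       truth = do.call(rbind, truth))
}

analyze_pairs <- function(criterion, practical_list, reference_id, sampler,
                          rope_mass, statistics, seed) {
  exercises <- sort(unique(criterion$exercise))
  # fixed processing order so fit seeds depend only on the cell identity,
  # not on how the device list was assembled
  devices <- sort(names(practical_list))
  cells <- list()
  missed <- list()
  for (dev in devices) {
    for (ex in exercises) {
      di <- match(dev, devices)
      ei <- match(ex, exercises)
      cell_seed <- subseed(seed, 1000L + 37L * di + ei)
      crit_ex <- criterion[criterion$exercise == ex, , drop = FALSE]
      prac_ex <- practical_list[[dev]]
      prac_ex <- prac_ex[prac_ex$exercise == ex, , drop = FALSE]
      cell_id <- paste(dev, ex, sep = ".")
      if (nrow(prac_ex) == 0) {
        cells[[cell_id]] <- list(device = dev, exercise = ex,
                                 estimable = FALSE)
        next
      }
      paired <- match_reps(crit_ex, prac_ex)
      missed[[cell_id]] <- data.frame(
        device = dev, exercise = ex,
        n_paired = attr(paired, "n_paired"),
        n_missed = attr(paired, "n_missed"),
        n_ghost = attr(paired, "n_ghost"),
        missed_rate = missed_rate(paired),
        stringsAsFactors = FALSE
      )
      enough <- nrow(paired) >= 4 && length(unique(paired$subject_id)) >= 2
      if (!enough) {
        cells[[cell_id]] <- list(device = dev, exercise = ex,
                                 estimable = FALSE)
        next
      }
      post <- list()
      need_cal <- any(c("intercept", "slope", "r2", "rmse") %in% statistics)
      if (need_cal) {
        fit1 <- fit_calibration(paired, sampler = sampler, seed = cell_seed)
        bl <- compute_bias_lines(fit1, rope_mass)
        if ("intercept" %in% statistics) post$intercept <- bl$intercept
        if ("slope" %in% statistics) post$slope <- bl$slope
        if ("r2" %in% statistics) post$r2 <- compute_r2(fit1, mass = rope_mass)
        if ("rmse" %in% statistics) {
          post$rmse <- compute_rmse(fit1, mass = rope_mass)
        }
      }
      if ("smb" %in% statistics) {
        fit2 <- fit_mean_bias(paired, sampler = sampler,
                              seed = subseed(cell_seed, 1L))
        post$smb <- compute_smb(fit2, mass = rope_mass)
      }
      cells[[cell_id]] <- list(device = dev, exercise = ex, estimable = TRUE,
                               posteriors = post)
    }
  }
  # reference-anchored ROPEs, then classification of every device
  report <- list()
  for (ex in exercises) {
    ref_cell <- cells[[paste(reference_id, ex, sep = ".")]]
    for (dev in devices) {
      cell <- cells[[paste(dev, ex, sep = ".")]]
      for (stat in statistics) {
        if (!isTRUE(cell$estimable) || is.null(cell$posteriors[[stat]])) {
          report[[length(report) + 1L]] <- data.frame(
            device = dev, exercise = ex, statistic = stat,
            mean = NA_real_, hdi_lower = NA_real_, hdi_upper = NA_real_,
            p_in_rope = NA_real_, p_below = NA_real_, p_above = NA_real_,
            label = "not_estimable", rhat_max = NA_real_, ess_min = NA_real_,
            flagged = NA, stringsAsFactors = FALSE
          )
          next
        }
        p <- cell$posteriors[[stat]]
        if (isTRUE(ref_cell$estimable) &&
            !is.null(ref_cell$posteriors[[stat]])) {
          rope <- build_rope(ref_cell$posteriors[[stat]], stat, rope_mass)
          p_in <- rope_probability(p, rope)
          p_below <- direction_probability(p, rope$low, "below")
          p_above <- direction_probability(p, rope$high, "above")
          label <- classify_equivalence(p_in, p_below, p_above, rope_mass)
        } else {
          p_in <- p_below <- p_above <- NA_real_
          label <- "no_reference"
        }
        report[[length(report) + 1L]] <- data.frame(
          device = dev, exercise = ex, statistic = stat,
          mean = p$mean, hdi_lower = p$hdi_lower, hdi_upper = p$hdi_upper,
          p_in_rope = p_in, p_below = p_below, p_above = p_above,
          label = label, rhat_max = p$rhat, ess_min = p$ess,
          flagged = p$flagged, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(report = do.call(rbind, report),
       missed = do.call(rbind, c(missed, list(make.row.names = FALSE))),
       cells = cells)
}

#' Run a full simulated validity study
#'
#' Simulates a cohort and its criterion trajectories, processes them through
#' the criterion kinematics pipeline, simulates every configured device,
#' pairs observations, fits the calibration and mean-bias models per device
#' and exercise, and classifies each statistic against the
#' reference-anchored ROPE.
#'
#' @param config A [study_config()].
#' @return An object of class `vbt_study`: `report` (per device x exercise x
#'   statistic: posterior mean, 95% HDI, ROPE membership and direction
#'   probabilities, label, diagnostics), `missed` (missed/ghost accounting
#'   per device x exercise), `velocity_summary`, `cohort`, `observations`,
#'   `config`.
#' @export
run_validity_study <- function(config = study_config()) {
  stage <- simulate_criterion_stage(config)
  devices <- config$devices
  practical <- list()
  for (i in seq_along(devices)) {
    practical[[devices[[i]]$device_id]] <-
      simulate_device(stage$truth, devices[[i]],
                      seed = subseed(config$seed, 50L + i))
  }
  ana <- analyze_pairs(stage$criterion, practical, config$reference_id,
                       config$sampler, config$rope_mass, config$statistics,
                       config$seed)
  all_obs <- rbind(stage$criterion, do.call(rbind, practical))
  structure(list(report = ana$report, missed = ana$missed,
                 velocity_summary = summarize_velocities(stage$criterion),
                 cohort = stage$cohort, observations = all_obs,
                 truth = stage$truth, config = config),
            class = "vbt_study")
}

#' Analyze an existing repetition table
#'
#' Skips simulation and kinematics: pairs, fits and classifies a
#' repetition-observation table that already contains criterion and
#' practical-device rows (e.g. one written by [write_rep_table()] or
#' exported from a study deposit).
#'
#' @param observations Path to a repetition table, or the data frame itself.
#' @param criterion_id Device id of the criterion rows.
#' @param reference_id Device id anchoring the ROPE.
#' @param sampler A [sampler_spec()].
#' @param rope_mass Posterior mass for HDIs and the decision rule.
#' @param statistics Validity statistics to compute.
#' @param seed Integer seed for the samplers.
#' @return A `vbt_study` (without cohort/truth elements).
#' @export
run_external <- function(observations, criterion_id, reference_id,
                         sampler = sampler_spec(), rope_mass = 0.95,
                         statistics = c("intercept", "slope", "r2", "rmse",
                                        "smb"),
                         seed = 1L) {
  if (is.character(observations)) {
    observations <- read_rep_table(observations)
  }
  validate_observations(observations)
  ids <- unique(observations$device_id)
  if (!criterion_id %in% ids || !reference_id %in% ids) {
    stop(sprintf("unknown device id; table contains: %s",
                 paste(ids, collapse = ", ")), call. = FALSE)
  }
  statistics <- match.arg(statistics, several.ok = TRUE)
  criterion <- observations[observations$device_id == criterion_id, ,
                            drop = FALSE]
  practical <- split(observations[observations$device_id != criterion_id, ,
                                  drop = FALSE],
                     observations$device_id[observations$device_id !=
                                              criterion_id])
  ana <- analyze_pairs(criterion, practical, reference_id, sampler,
                       rope_mass, statistics, seed)
  structure(list(report = ana$report, missed = ana$missed,
                 velocity_summary = summarize_velocities(criterion),
                 observations = observations,
                 config = list(criterion_id = criterion_id,
                               reference_id = reference_id,
                               sampler = sampler, rope_mass = rope_mass,
                               statistics = statistics, seed = seed)),
            class = "vbt_study")
}

#' @export
print.vbt_study <- function(x, ...) {
  vs <- x$velocity_summary
  cat(sprintf("Validity study: %d repetitions, criterion MV %.2f +/- %.2f [%.2f-%.2f] m/s\n",
              vs$n, vs$mean, vs$sd, vs$min, vs$max))
  cat("\nMissed/ghost repetitions:\n")
  print(x$missed, row.names = FALSE)
  cat("\nEquivalence report (reference-anchored ROPE):\n")
  rep <- x$report
  rep$summary <- sprintf("%.3f [%.3f, %.3f]", rep$mean, rep$hdi_lower,
                         rep$hdi_upper)
  print(rep[c("device", "exercise", "statistic", "summary", "p_in_rope",
              "label")], row.names = FALSE, digits = 3)
  invisible(x)
}
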