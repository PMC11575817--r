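# Shared fixtures, built in code at test time.

# Reduced sampler for tests: 2 chains x (500 adapt + 1000 warmup + 750 kept)
# converges reliably on these problem sizes while keeping runtime low.
quick_sampler <- function() sampler_spec(chains = 2, adapt = 500,
                                         warmup = 1000, draws = 750)

# Paired criterion/practical dataset simulated straight at the mean-velocity
# level (no trajectories): n_subjects lifters x n_reps repetitions with true
# MVs spread over the study's velocity range, observed through a device with
# the given error profile.
make_paired <- function(n_subjects = 20, n_reps = 30, alpha = 0, beta = 1,
                        sigma = 0.001, re_sd = c(0, 0), re_cor = 0,
                        miss_prob = 0, seed = 1) {
  cohort_ids <- sprintf("S%02d", seq_len(n_subjects))
  truth <- do.call(rbind, lapply(seq_len(n_subjects), function(i) {
    mv <- with_test_seed(seed * 1000 + i, runif(n_reps, 0.15, 0.95))
    data.frame(subject_id = cohort_ids[i], exercise = "squat",
               load_pct = seq_len(n_reps), set_index = seq_len(n_reps),
               rep_index = 1L, true_mv = mv, stringsAsFactors = FALSE)
  }))
  prof <- device_profile("dev", alpha = alpha, beta = beta, sigma = sigma,
                         re_sd = re_sd, re_cor = re_cor,
                         miss_prob = miss_prob)
  prac <- simulate_device(truth, prof, seed = seed + 7)
  crit <- truth
  crit$device_id <- "vicon"
  crit$mean_velocity <- crit$true_mv
  crit$status <- "ok"
  crit$true_mv <- NULL
  match_reps(crit, prac)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Minimal synthetic repetition-observation table builder.
make_obs <- function(subject = "S01", exercise = "squat", load = 50,
                     set = 1, rep = 1, device = "dev", mv = 0.5,
                     status = "ok") {
  data.frame(subject_id = subject, exercise = exercise, load_pct = load,
             set_index = set, rep_index = rep, device_id = device,
             mean_velocity = ifelse(status == "ok", mv, NA_real_),
             status = status, stringsAsFactors = FALSE)
}
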