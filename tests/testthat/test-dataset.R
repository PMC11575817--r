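crit_10 <- function() {
  do.call(rbind, lapply(1:10, function(i) {
    make_obs(load = 40 + 5 * i, set = i, device = "vicon", mv = 0.3 + i / 50)
  }))
}

test_that("order-based matching pairs complete streams fully", {
  crit <- crit_10()
  prac <- crit_10()
  prac$device_id <- "app"
  prac$mean_velocity <- prac$mean_velocity + 0.01
  paired <- match_reps(crit, prac)
  expect_equal(attr(paired, "n_paired"), 10)
  expect_equal(attr(paired, "n_missed"), 0)
  expect_equal(attr(paired, "n_ghost"), 0)
  expect_equal(paired$practical_mv - paired$criterion_mv, rep(0.01, 10))
})

test_that("missed and ghost repetitions are accounted for separately", {
  crit <- crit_10()
  prac <- crit_10()
  prac$device_id <- "app"
  prac$status[c(2, 5, 9)] <- "missed"
  prac$mean_velocity[c(2, 5, 9)] <- NA
  ghosts <- rbind(
    make_obs(load = 45, set = 1, rep = 2, device = "app", status = "ghost"),
    make_obs(load = 50, set = 2, rep = 2, device = "app", status = "ghost")
  )
  paired <- match_reps(crit, rbind(prac, ghosts))
  expect_equal(attr(paired, "n_paired"), 7)
  expect_equal(attr(paired, "n_missed"), 3)
  expect_equal(attr(paired, "n_ghost"), 2)
  # conservation: criterion reps = paired + missed
  expect_equal(attr(paired, "n_paired") + attr(paired, "n_missed"),
               sum(crit$status == "ok"))
  # matching never crosses set boundaries
  expect_true(all(paired$set_index %in% which(prac$status == "ok")))
})

test_that("missed rate is n_missed over performed repetitions", {
  crit <- crit_10()
  prac <- crit_10()
  prac$device_id <- "app"
  expect_equal(missed_rate(match_reps(crit, prac)), 0)
  prac$status[1:3] <- "missed"
  prac$mean_velocity[1:3] <- NA
  expect_equal(missed_rate(match_reps(crit, prac)), 0.3)
  # the published-style accounting: 3 missed of 199 performed
  expect_equal(3 / 199, 0.01507538, tolerance = 1e-6)
  prac$status <- "missed"
  prac$mean_velocity <- NA
  expect_equal(missed_rate(match_reps(crit, prac)), 1)
})

test_that("velocity summaries use the n-1 denominator and flag single values", {
  s <- summarize_velocities(velocities = c(0.2, 0.4, 0.6))
  expect_equal(s$mean, 0.4)
  expect_equal(s$sd, 0.2)
  expect_equal(c(s$min, s$max), c(0.2, 0.6))
  one <- summarize_velocities(velocities = 0.5)
  expect_equal(one$sd, 0, ignore_attr = TRUE)
  expect_true(isTRUE(attr(one$sd, "sd_undefined")))
  obs <- rbind(make_obs(mv = 0.3), make_obs(set = 2, mv = 0.5, load = 55),
               make_obs(set = 3, load = 60, status = "missed"))
  expect_equal(summarize_velocities(obs)$n, 2)
})

test_that("rep tables and trajectories round-trip through delimited text", {
  obs <- rbind(crit_10(),
               make_obs(load = 95, set = 11, status = "missed"),
               make_obs(load = 100, set = 12, status = "ghost"))
  obs$device_id <- "vicon"
  path <- tempfile(fileext = ".csv")
  write_rep_table(obs, path)
  back <- read_rep_table(path)
  expect_equal(back$mean_velocity, obs$mean_velocity)
  expect_equal(back$status, obs$status)
  expect_equal(back$subject_id, obs$subject_id)
  expect_equal(back$load_pct, obs$load_pct)

  tr <- simulate_trajectory("squat", 0.6, seed = 3)
  tpath <- tempfile(fileext = ".csv")
  write_trajectory(tr, tpath)
  tback <- read_trajectory(tpath)
  expect_equal(tback$z_m, tr$z_m, tolerance = 1e-9)
  expect_equal(attr(tback, "sampling_rate"), 200, tolerance = 1e-6)
})

test_that("schema violations are rejected with informative messages", {
  crit <- crit_10()
  dup <- rbind(crit, crit[1, ])
  expect_error(match_reps(dup, crit_10()), "duplicate")
  bad <- crit
  bad$status[3] <- "missed"  # velocity still present
  expect_error(match_reps(bad, crit_10()), "row 3")
  neg <- crit
  neg$mean_velocity[2] <- -0.1
  expect_error(match_reps(neg, crit_10()), "positive")
  two_dev <- crit_10()
  two_dev$device_id[1] <- "other"
  expect_error(match_reps(crit, two_dev), "one device")
})
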