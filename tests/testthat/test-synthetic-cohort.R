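test_that("config invariants are enforced", {
  expect_error(cohort_config(100, phase_slopes = c(-0.1, 0.1)),
               "phase count")
  expect_error(cohort_config(100, true_changepoints = c(53, 33),
                             phase_slopes = c(1, 2, 3)),
               "strictly increasing")
  expect_error(cohort_config(100, true_changepoints = c(19, 53)),
               "inside age_range")
  expect_error(cohort_config(0), "n_participants")
  expect_error(cohort_config(10, long_outlier_rate = 1.2), "long_outlier_rate")
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- cohort_config(500, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$participants, b$truth$participants)
  c <- generate_cohort(cohort_config(500, seed = 8))
  expect_false(identical(a$records$sleep_hours, c$records$sleep_hours))
})

test_that("noise-free limit reproduces the trend exactly", {
  cfg <- cohort_config(2000, residual_sd = 0, gender_offset = 0,
                       country_intercept_sd = 0, round_sleep = FALSE,
                       long_outlier_rate = 0, seed = 3)
  g <- generate_cohort(cfg)
  expect_equal(g$records$sleep_hours, sleep_trend(cfg, g$records$age),
               tolerance = 1e-12)
  # and the per-age signal is then exactly the trend
  sig <- per_age_mean_signal(g$records)
  expect_equal(sig$values, sleep_trend(cfg, sig$positions), tolerance = 1e-12)
})

test_that("per-age mean curve matches its Monte-Carlo expectation", {
  # Expected per-age mean = trend + realized country-mix offset + gender-mix
  # offset (computable exactly from the generated records + truth). Each
  # age's deviation is bounded by 4 x its standard error. Rounding to
  # integer hours is mean-preserving to well below that tolerance, so the
  # check runs on unfiltered records with outlier contamination disabled.
  cfg <- cohort_config(200000, long_outlier_rate = 0, seed = 1)
  g <- generate_cohort(cfg)
  r <- g$records
  cmeta <- g$truth$countries
  ceff <- cmeta$intercept[match(r$country, cmeta$country)] +
    cmeta$cluster_shift[match(r$country, cmeta$country)]
  geff <- ifelse(r$gender == "woman", +cfg$gender_offset / 2,
                 -cfg$gender_offset / 2)
  expected <- sleep_trend(cfg, r$age) + ceff + geff
  dt <- data.table::data.table(age = r$age, s = r$sleep_hours, e = expected)
  agg <- dt[, .(m = mean(s), e = mean(e), se = sd(s) / sqrt(.N)), by = age]
  expect_true(all(abs(agg$m - agg$e) <= 4 * agg$se))
})

test_that("marginal SD of filtered sleep is close to 1.07 h", {
  g <- generate_cohort(cohort_config(120000, seed = 5))
  f <- apply_inclusion_filters(g$records, filter_config())
  expect_lt(abs(sd(f$records$sleep_hours) - 1.07), 0.1)
  expect_lt(abs(mean(f$records$sleep_hours) - 7.01), 0.1)
})

test_that("out-of-range responses exist at roughly the emulated rate", {
  g <- generate_cohort(cohort_config(120000, seed = 6))
  s <- g$records$sleep_hours
  frac_low <- mean(s < 5)
  frac_high <- mean(s > 10)
  expect_gt(frac_low, 0.004)   # ~0.9% emulated
  expect_lt(frac_low, 0.02)
  expect_gt(frac_high, 0.002)  # ~0.6% emulated
  expect_lt(frac_high, 0.015)
  expect_true(all(s >= 4 & s <= 12))
  expect_true(all(s == round(s)))
})

test_that("women's stratified age curve sits above men's at every bin", {
  g <- generate_cohort(cohort_config(200000, seed = 9))
  f <- apply_inclusion_filters(g$records, filter_config())
  curves <- bin_age_curve(f$records, 3, group_by = "gender")
  w <- curves[curves$group == "woman", ]
  m <- curves[curves$group == "man", ]
  expect_identical(w$age_lo, m$age_lo)
  expect_true(all(w$mean_sleep > m$mean_sleep))
})

test_that("cohort CSV and ground-truth JSON round-trip", {
  g <- generate_cohort(cohort_config(50, seed = 10))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(g$records, tmp)
  back <- read_cohort_csv(tmp)
  expect_equal(back$sleep_hours, g$records$sleep_hours)
  expect_equal(back$country, g$records$country)
  gt <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(g$truth, gt)
  parsed <- jsonlite::read_json(gt, simplifyVector = TRUE)
  expect_equal(parsed$true_changepoints, c(33, 53))
  expect_length(parsed$participants$participant_id, 50)
  expect_equal(parsed$skill_link$peak_hours, 7)
})

test_that("trajectory generator honors its limits and determinism", {
  g <- generate_cohort(cohort_config(30, seed = 12))
  tc <- trajectory_config(seed = 13)
  t1 <- generate_trajectories(g$records, tc, g$truth)
  t2 <- generate_trajectories(g$records, tc, g$truth)
  expect_identical(t1, t2)
  expect_identical(sort(unique(t1$level)), c(1L, 2L, 6L, 7L, 8L, 11L))
  # empty input -> empty output
  empty <- generate_trajectories(g$records[0, ], tc, g$truth)
  expect_equal(nrow(empty), 0)
  # missing skills -> error
  bad <- g$records
  bad$participant_id[1] <- "UNKNOWN"
  expect_error(generate_trajectories(bad, tc, g$truth), "missing latent")
})

test_that("perfect skill and zero noise give the exact checkpoint polyline", {
  g <- generate_cohort(cohort_config(5, seed = 14))
  g$truth$participants$nav_skill[] <- 1
  g$truth$participants$motor_skill[] <- 1
  tc <- trajectory_config(motor_noise_sd = 0, seed = 15)
  traj <- generate_trajectories(g$records, tc, g$truth)
  specs <- default_level_specs()
  for (spec in specs) {
    ideal <- trajectory_length(spec$checkpoints)
    sub <- traj[traj$level == spec$level &
                  traj$participant_id == g$records$participant_id[1], ]
    expect_equal(trajectory_length(sub), ideal, tolerance = 1e-9)
  }
})

test_that("lower navigation skill means longer wayfinding paths on average", {
  g <- generate_cohort(cohort_config(600, seed = 16))
  half <- g
  half$truth$participants$nav_skill[] <- 0.5
  half$truth$participants$motor_skill[] <- 0.9
  full <- g
  full$truth$participants$nav_skill[] <- 1.0
  full$truth$participants$motor_skill[] <- 0.9
  tc <- trajectory_config(seed = 17)
  len_of <- function(gen) {
    traj <- generate_trajectories(gen$records, tc, gen$truth)
    wf <- traj[traj$level == 6, ]
    dt <- data.table::as.data.table(wf)
    mean(dt[, .(L = sum(sqrt(diff(x)^2 + diff(y)^2))),
            by = participant_id]$L)
  }
  expect_gt(len_of(half), len_of(full))
})
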