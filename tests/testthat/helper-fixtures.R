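# Shared fixtures, built in code. Expensive synthetic datasets are created
# lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# A mid-sized cohort with trajectories, used by the navigation and pipeline
# tests (n chosen so scoring + model fits stay fast but group cells are
# well populated).
scored_cohort <- function() {
  if (is.null(.fixtures$scored)) {
    g <- generate_cohort(cohort_config(6000, seed = 101))
    f <- apply_inclusion_filters(g$records, filter_config(min_country_n = 1))
    traj <- generate_trajectories(f$records, trajectory_config(seed = 102),
                                  g$truth)
    scores <- compute_tp_wf(traj)
    .fixtures$scored <- list(gen = g, records = f$records, traj = traj,
                             scores = scores)
  }
  .fixtures$scored
}

# Hand-written toy cohort rows.
toy_records <- function() {
  data.frame(
    participant_id = sprintf("T%02d", 1:10),
    age = c(25, 30, 75, 40, 45, 50, 55, 60, 65, 70),
    gender = rep(c("man", "woman"), 5),
    education = rep(c("secondary", "tertiary"), 5),
    home_env = rep(c("city", "non-city"), 5),
    commute = rep(c("<30min", "30-60min", ">60min"), length.out = 10),
    country = c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C"),
    sleep_hours = c(11, 11, 7, 4, 7, 8, 6, 9, 7, 7),
    stringsAsFactors = FALSE
  )
}

# Random short signal for oracle cross-checks.
random_signal <- function(n, scale = 1) {
  as_signal(sort(sample(seq_len(5 * n), n)), round(stats::rnorm(n, 0, scale), 3))
}

expect_same_segmentation <- function(a, b, tol = 1e-9) {
  expect_equal(a$changepoints, b$changepoints)
  expect_equal(a$deviation, b$deviation, tolerance = tol)
  expect_equal(a$total_sse, b$total_sse, tolerance = tol)
}
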