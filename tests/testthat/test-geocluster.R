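test_that("packaged country cluster table is well-formed", {
  cc <- country_clusters()
  expect_true(all(c("country", "code", "maddison_cluster",
                    "cultural_cluster", "weird") %in% names(cc)))
  expect_equal(length(unique(cc$maddison_cluster)), 7)
  expect_equal(length(unique(cc$cultural_cluster)), 11)
  expect_false(any(duplicated(cc$code)))
  expect_type(cc$weird, "logical")
  expect_true("GB" %in% cc$code)   # England carried under the UK code
})

test_that("cluster F equals a from-scratch sums-of-squares oracle", {
  set.seed(81)
  n <- 30
  recs <- data.frame(
    participant_id = as.character(1:n),
    age = sample(19:70, n, TRUE),
    gender = sample(c("man", "woman"), n, TRUE),
    education = "secondary", home_env = "city", commute = "<30min",
    country = sample(c("A", "B", "C", "D"), n, TRUE),
    sleep_hours = rnorm(n, 7, 1))
  cmap <- c(A = "c1", B = "c1", C = "c2", D = "c3")
  res <- cluster_anova_f(recs, cmap)
  # oracle: explicit projection algebra, solved via normal equations
  y <- recs$sleep_hours
  xr <- cbind(1, recs$age, as.numeric(recs$gender == "woman"))
  cl <- cmap[recs$country]
  xf <- cbind(xr, as.numeric(cl == "c2"), as.numeric(cl == "c3"))
  rss <- function(X) {
    b <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% b)^2)
  }
  df1 <- 2; df2 <- n - ncol(xf)
  f_oracle <- ((rss(xr) - rss(xf)) / df1) / (rss(xf) / df2)
  expect_equal(res$f, f_oracle, tolerance = 1e-8)
  expect_equal(res$df1, df1)
  expect_equal(res$df2, df2)
  expect_error(cluster_anova_f(recs, c(A = "c1", B = "c1", C = "c2")),
               "unmapped")
})

test_that("cluster F is invariant to relabeling cluster names", {
  g <- generate_cohort(cohort_config(3000, seed = 82))
  cc <- country_clusters()
  cmap <- stats::setNames(cc$maddison_cluster, cc$code)
  f1 <- cluster_anova_f(g$records, cmap)
  relabel <- stats::setNames(paste0("X", as.integer(factor(cmap))), names(cmap))
  f2 <- cluster_anova_f(g$records, relabel)
  expect_equal(f1$f, f2$f, tolerance = 1e-10)
})

test_that("permutation null is deterministic and p has the right floor", {
  g <- generate_cohort(cohort_config(2000, seed = 83))
  cc <- country_clusters()
  cmap <- stats::setNames(cc$maddison_cluster, cc$code)
  p1 <- permutation_null(g$records, cmap, n_shuffles = 50, seed = 84)
  p2 <- permutation_null(g$records, cmap, n_shuffles = 50, seed = 84)
  expect_identical(p1$null_f, p2$null_f)
  expect_gte(p1$p, 1 / 51)
  expect_lte(p1$p, 1)
  expect_error(permutation_null(g$records, cmap, n_shuffles = 0), "n_shuffles")
  # participant-level shuffle gives a null centered near 1
  pp <- permutation_null(g$records, cmap, n_shuffles = 100, seed = 85,
                         level = "participant")
  expect_lt(abs(mean(pp$null_f) - 1), 0.3)
})

test_that("a strong cluster shift is detected against its permutation null", {
  g <- generate_cohort(cohort_config(20000, cluster_shift_sd = 0.3, seed = 86))
  cc <- country_clusters()
  cmap <- stats::setNames(cc$maddison_cluster, cc$code)
  po <- permutation_null(g$records, cmap, n_shuffles = 100, seed = 87,
                         level = "participant")
  expect_gt(po$observed_f, max(po$null_f))
  expect_equal(po$p, 1 / 101)
})

test_that("latitude correlation: exact linearity, shuffle null, sign flip", {
  summ <- data.frame(mean_sleep = 6.5 + 0.01 * c(5, 15, 25, 40, 60),
                     abs_latitude = c(5, 15, 25, 40, 60))
  expect_equal(latitude_correlation(summ)$r, 1, tolerance = 1e-12)
  flipped <- summ
  flipped$mean_sleep <- 8 - 0.01 * flipped$abs_latitude
  expect_equal(latitude_correlation(flipped)$r, -1, tolerance = 1e-12)
  set.seed(88)
  rs <- replicate(50, {
    sh <- summ
    sh$abs_latitude <- sample(sh$abs_latitude)
    latitude_correlation(sh)$r
  })
  expect_lt(abs(mean(rs)), 0.35)
  expect_error(latitude_correlation(summ[1:2, ]), ">= 3 countries")
  const <- summ; const$mean_sleep <- 7
  expect_error(latitude_correlation(const), "constant")
})

test_that("country-level OLS matches a normal-equations oracle", {
  summ <- data.frame(
    country = LETTERS[1:6],
    mean_sleep = c(6.9, 7.1, 7.3, 6.8, 7.0, 7.2),
    conditional_mode = c(-0.1, 0.1, 0.3, -0.2, 0, 0.2),
    gdp_per_capita = c(10000, 20000, 15000, 40000, 30000, 8000),
    abs_latitude = c(10, 45, 60, 35, 50, 5),
    weird = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
  tab <- gdp_latitude_regression(summ)
  X <- cbind(1, summ$gdp_per_capita, summ$abs_latitude)
  beta <- solve(t(X) %*% X, t(X) %*% summ$mean_sleep)
  expect_equal(tab$estimate, as.numeric(beta), tolerance = 1e-8)
  resid <- summ$mean_sleep - X %*% beta
  s2 <- sum(resid^2) / (6 - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(tab$se, as.numeric(se), tolerance = 1e-8)
  expect_equal(tab$t, tab$estimate / tab$se, tolerance = 1e-10)
  expect_equal(unique(tab$df), 3)
  tw <- gdp_latitude_regression(summ, include_weird = TRUE)
  expect_equal(nrow(tw), 4)
  expect_equal(unique(tw$df), 2)
  # conditional-mode response uses that column
  tm <- gdp_latitude_regression(summ, response = "conditional_mode")
  expect_equal(nrow(tm), 3)
})

test_that("generator latitude effect is recovered; absent GDP effect is not", {
  cfg <- cohort_config(40000, latitude_effect = 0.15, gdp_effect = 0,
                       country_intercept_sd = 0.05, seed = 89)
  g <- generate_cohort(cfg)
  f <- apply_inclusion_filters(g$records, filter_config(min_country_n = 1))
  summ <- country_summaries(
    f$records,
    g$truth$countries[, c("country", "abs_latitude", "gdp_per_capita",
                          "maddison_cluster", "cultural_cluster", "weird")])
  tab <- gdp_latitude_regression(summ)
  lat <- tab[tab$term == "abs_latitude", ]
  gdp <- tab[tab$term == "gdp_per_capita", ]
  expect_true(lat$ci_low > 0)                       # latitude effect found
  expect_true(gdp$ci_low <= 0 && 0 <= gdp$ci_high)  # no GDP effect invented
  expect_gt(latitude_correlation(summ)$r, 0.5)
  # adding an uninformative WEIRD flag leaves the inference unchanged
  tw <- gdp_latitude_regression(summ, include_weird = TRUE)
  expect_true(tw[tw$term == "abs_latitude", "ci_low"] > 0)
})

test_that("subgroup change points: partition identity and gender invariance", {
  g <- generate_cohort(cohort_config(150000, seed = 90))
  f <- apply_inclusion_filters(g$records, filter_config())
  r <- f$records
  r$all <- "all"
  whole <- subgroup_changepoints(r, "all")
  direct <- optimal_segmentation(per_age_mean_signal(r), 0.02)
  expect_identical(whole$all$changepoints, direct$changepoints)
  # both genders share the trend: detected change points agree closely
  by_gender <- subgroup_changepoints(r, "gender")
  expect_length(by_gender, 2)
  cps <- vapply(by_gender, function(s) length(s$changepoints), numeric(1))
  expect_true(all(cps == 2))
  gap <- abs(by_gender$man$changepoints - by_gender$woman$changepoints)
  expect_true(all(gap <= 6))
})
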