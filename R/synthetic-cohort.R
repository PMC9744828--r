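#' Configuration of the synthetic cohort generator
#'
#' Describes the generative world the package's validation suite runs
#' against: a three-phase piecewise-linear mean sleep-vs-age trend, a gender
#' offset, country random intercepts (optionally structured by supra-national
#' cluster, latitude and GDP), integer-hour sleep reporting with a small
#' out-of-range fraction, and a latent per-participant navigation and motor
#' skill, with the navigation skill linked to reported sleep through an
#' inverted-U (quadratic) relation that peaks at 7 h and is concentrated in
#' the oldest age group.
#'
#' Defaults encode the study conditions the generator emulates: ages 19-70,
#' change points at 33 and 53 years, phase slopes -0.025 / -0.005 / +0.012
#' h/year starting from 7.35 h at age 19 (giving phase means ~7.35 -> 7.0 ->
#' 6.9 -> 7.1 h), a +0.13 h woman-minus-man offset, 63 countries with
#' intercept SD 0.2 h, and a residual SD of 1.04 h chosen so that the
#' marginal SD of filtered integer-hour responses is approximately 1.07 h.
#'
#' @param n_participants number of participants to draw.
#' @param age_range inclusive integer age range, default `c(19, 70)`.
#' @param true_changepoints ages at which the trend slope changes (a change
#'   point at age a means the new slope applies from age a onwards);
#'   default `c(33, 53)`.
#' @param phase_slopes h/year slope per phase; must have
#'   `length(true_changepoints) + 1` entries.
#' @param intercept_at_min mean sleep (hours) at the youngest age.
#' @param gender_offset hours, woman minus man; applied symmetrically
#'   (+offset/2 / -offset/2) so the unstratified per-age mean equals the
#'   trend.
#' @param n_countries number of countries (<= 64 draws codes and cluster
#'   labels from the packaged country-cluster table).
#' @param country_intercept_sd SD (hours) of the zero-mean country random
#'   intercepts, after any latitude/GDP structure.
#' @param cluster_shifts optional named vector of extra mean shifts (hours)
#'   per Maddison cluster; default all zero (no cluster signal).
#' @param cluster_shift_sd if `cluster_shifts` is `NULL` and this is > 0,
#'   cluster shifts are drawn from N(0, sd).
#' @param latitude_effect,gdp_effect hours per 1 SD of country absolute
#'   latitude / log GDP per capita contributed to the country intercept;
#'   both default 0 (purely random intercepts).
#' @param residual_sd SD (hours) of the participant-level Gaussian noise on
#'   the latent continuous sleep value.
#' @param round_sleep round the latent value to the nearest integer hour
#'   (the reporting model); `FALSE` keeps it continuous.
#' @param sleep_support integer support to which rounded responses are
#'   clamped, default `c(4, 12)`; values outside the 5-10 h inclusion window
#'   exist so the inclusion filter has work to do.
#' @param long_outlier_rate probability that a response is replaced by an
#'   erroneous long value (11 or 12 h), emulating the small excess of
#'   implausible long reports; default 0.006.
#' @param p_woman,p_tertiary,p_city probabilities of the woman / tertiary /
#'   city levels; defaults follow the cohort composition the generator
#'   emulates (48% women, 72% tertiary, 30% city).
#' @param commute_probs probabilities of the three commute bands
#'   (<30min, 30-60min, >60min).
#' @param skill_link_quad named quadratic coefficients (per (hour)^2 of
#'   sleep - 7) of the sleep -> navigation-skill link for the young, middle
#'   and older age groups; negative values give an inverted U with its peak
#'   at 7 h. Default `c(young = -0.005, middle = -0.010, older = -0.030)`:
#'   present everywhere, concentrated in the oldest group.
#' @param skill_link_lin linear coefficients per group (default 0: peak
#'   exactly at 7 h).
#' @param skill_sd SD of the latent navigation-skill noise.
#' @param country_size_sdlog log-SD of the lognormal country sampling
#'   weights (0 = equal-sized countries).
#' @param age_weights optional per-age sampling weights (age pyramid);
#'   default uniform.
#' @param seed RNG seed; identical seeds give byte-identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_participants,
                          age_range = c(19L, 70L),
                          true_changepoints = c(33, 53),
                          phase_slopes = c(-0.025, -0.005, 0.012),
                          intercept_at_min = 7.35,
                          gender_offset = 0.13,
                          n_countries = 63,
                          country_intercept_sd = 0.2,
                          cluster_shifts = NULL,
                          cluster_shift_sd = 0,
                          latitude_effect = 0,
                          gdp_effect = 0,
                          residual_sd = 1.04,
                          round_sleep = TRUE,
                          sleep_support = c(4L, 12L),
                          long_outlier_rate = 0.006,
                          p_woman = 0.478,
                          p_tertiary = 0.72,
                          p_city = 0.304,
                          commute_probs = c(0.40, 0.348, 0.252),
                          skill_link_quad = c(young = -0.005,
                                              middle = -0.010,
                                              older = -0.030),
                          skill_link_lin = c(young = 0, middle = 0, older = 0),
                          skill_sd = 0.10,
                          country_size_sdlog = 0.8,
                          age_weights = NULL,
                          seed = NULL) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    age_range = as.integer(age_range),
    true_changepoints = as.numeric(true_changepoints),
    phase_slopes = as.numeric(phase_slopes),
    intercept_at_min = intercept_at_min,
    gender_offset = gender_offset,
    n_countries = as.integer(n_countries),
    country_intercept_sd = country_intercept_sd,
    cluster_shifts = cluster_shifts,
    cluster_shift_sd = cluster_shift_sd,
    latitude_effect = latitude_effect,
    gdp_effect = gdp_effect,
    residual_sd = residual_sd,
    round_sleep = isTRUE(round_sleep),
    sleep_support = as.numeric(sleep_support),
    long_outlier_rate = long_outlier_rate,
    p_woman = p_woman,
    p_tertiary = p_tertiary,
    p_city = p_city,
    commute_probs = commute_probs,
    skill_link_quad = skill_link_quad,
    skill_link_lin = skill_link_lin,
    skill_sd = skill_sd,
    country_size_sdlog = country_size_sdlog,
    age_weights = age_weights,
    seed = seed
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  if (length(cfg$age_range) != 2 || diff(cfg$age_range) <= 0) {
    stop("age_range must be two increasing ages", call. = FALSE)
  }
  k <- length(cfg$true_changepoints)
  if (length(cfg$phase_slopes) != k + 1) {
    stop("phase count must equal change-point count + 1 (got ",
         length(cfg$phase_slopes), " slopes for ", k, " change points)",
         call. = FALSE)
  }
  if (k > 0) {
    if (any(diff(cfg$true_changepoints) <= 0)) {
      stop("change points must be strictly increasing", call. = FALSE)
    }
    if (min(cfg$true_changepoints) <= cfg$age_range[1] ||
        max(cfg$true_changepoints) >= cfg$age_range[2]) {
      stop("change points must lie strictly inside age_range", call. = FALSE)
    }
  }
  if (cfg$residual_sd <= 0 && cfg$round_sleep) {
    # residual_sd == 0 only allowed in the (unrounded) noise-free limit check
  }
  if (cfg$residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  if (cfg$long_outlier_rate < 0 || cfg$long_outlier_rate >= 1) {
    stop("long_outlier_rate must be in [0, 1)", call. = FALSE)
  }
  grp_names <- c("young", "middle", "older")
  if (!all(grp_names %in% names(cfg$skill_link_quad)) ||
      !all(grp_names %in% names(cfg$skill_link_lin))) {
    stop("skill_link_quad and skill_link_lin must be named with ",
         "'young', 'middle', 'older'", call. = FALSE)
  }
  invisible(cfg)
}

#' Piecewise-linear mean sleep trend
#'
#' Evaluates the generator's population mean reported sleep duration at the
#' given ages: continuous piecewise-linear with slope `phase_slopes[k]` over
#' phase k and slope changes exactly at the configured change points (the
#' new slope applies from the change-point age onwards).
#'
#' @param config a `cohort_config`.
#' @param age numeric vector of ages.
#' @return hours of sleep, same length as `age`.
#' @export
sleep_trend <- function(config, age) {
  knots <- c(config$age_range[1], config$true_changepoints, config$age_range[2])
  out <- rep(config$intercept_at_min, length(age))
  for (k in seq_along(config$phase_slopes)) {
    lo <- knots[k]; hi <- knots[k + 1]
    out <- out + config$phase_slopes[k] * pmax(0, pmin(age, hi) - lo)
  }
  # extrapolate flat outside range (not used by the generator itself)
  out
}

# Country table for a synthetic cohort: codes and cluster labels come from
# the packaged country-cluster table when n_countries fits it, otherwise
# generic codes with round-robin cluster labels.
synth_country_table <- function(cfg) {
  k <- cfg$n_countries
  packaged <- tryCatch(country_clusters(), error = function(e) NULL)
  if (!is.null(packaged) && k <= nrow(packaged)) {
    tab <- packaged[seq_len(k),
                    c("code", "maddison_cluster", "cultural_cluster", "weird")]
    names(tab)[1] <- "country"
  } else {
    mad <- paste0("M", 1:7)
    cul <- paste0("K", 1:11)
    tab <- data.frame(
      country = sprintf("C%03d", seq_len(k)),
      maddison_cluster = mad[(seq_len(k) - 1L) %% 7L + 1L],
      cultural_cluster = cul[(seq_len(k) - 1L) %% 11L + 1L],
      weird = seq_len(k) <= round(0.3 * k),
      stringsAsFactors = FALSE
    )
  }
  rownames(tab) <- NULL
  tab
}

#' Generate a synthetic participant cohort with known ground truth
#'
#' Draws `n_participants` records (age, gender, education, home environment,
#' commute band, country, integer reported sleep hours) from the generative
#' model described in [cohort_config()], together with the latent navigation
#' and motor skill of every participant and all country-level parameters.
#'
#' The latent continuous sleep value is
#' `trend(age) +/- gender_offset/2 + country intercept + cluster shift +
#' N(0, residual_sd)`, rounded to the nearest integer hour and clamped to
#' `sleep_support`; a small fraction (`long_outlier_rate`) of responses is
#' replaced by an erroneous 11 or 12 h report. The latent navigation skill is
#' `0.5 + b1_g (sleep - 7) + b2_g (sleep - 7)^2 + N(0, skill_sd)` (clamped to
#' [0.02, 0.98]) with group-specific coefficients, the motor skill an
#' independent clamped N(0.6, 0.15).
#'
#' @param config a [cohort_config()].
#' @return list with `records` (data.frame, one row per participant) and
#'   `truth` (list: trend parameters, country table with intercepts,
#'   latitude, GDP, clusters and WEIRD flags, skill-link coefficients, and
#'   per-participant latent skills).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_participants
  ages_all <- seq(cfg$age_range[1], cfg$age_range[2])

  # ---- countries -----------------------------------------------------------
  ctab <- synth_country_table(cfg)
  k <- nrow(ctab)
  w <- if (cfg$country_size_sdlog > 0) {
    stats::rlnorm(k, 0, cfg$country_size_sdlog)
  } else rep(1, k)
  w <- w / sum(w)
  ctab$weight <- w
  ctab$abs_latitude <- stats::runif(k, 0, 65)
  ctab$gdp_per_capita <- exp(stats::rnorm(k, log(20000), 0.8))
  safe_z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  lat_z <- safe_z(ctab$abs_latitude)
  gdp_z <- safe_z(log(ctab$gdp_per_capita))
  ctab$intercept <- cfg$latitude_effect * lat_z + cfg$gdp_effect * gdp_z +
    stats::rnorm(k, 0, cfg$country_intercept_sd)

  clusters <- sort(unique(ctab$maddison_cluster))
  shifts <- cfg$cluster_shifts
  if (is.null(shifts)) {
    shifts <- if (cfg$cluster_shift_sd > 0) {
      stats::setNames(stats::rnorm(length(clusters), 0, cfg$cluster_shift_sd),
                      clusters)
    } else {
      stats::setNames(rep(0, length(clusters)), clusters)
    }
  } else {
    missing_cl <- setdiff(clusters, names(shifts))
    if (length(missing_cl)) {
      stop("cluster_shifts is missing clusters: ",
           paste(missing_cl, collapse = ", "), call. = FALSE)
    }
    shifts <- shifts[clusters]
  }
  ctab$cluster_shift <- shifts[ctab$maddison_cluster]

  # ---- demographics --------------------------------------------------------
  age <- if (is.null(cfg$age_weights)) {
    sample(ages_all, n, replace = TRUE)
  } else {
    stopifnot(length(cfg$age_weights) == length(ages_all))
    sample(ages_all, n, replace = TRUE, prob = cfg$age_weights)
  }
  gender <- ifelse(stats::runif(n) < cfg$p_woman, "woman", "man")
  education <- ifelse(stats::runif(n) < cfg$p_tertiary, "tertiary", "secondary")
  home_env <- ifelse(stats::runif(n) < cfg$p_city, "city", "non-city")
  commute <- sample(c("<30min", "30-60min", ">60min"), n, replace = TRUE,
                    prob = cfg$commute_probs)
  ci <- sample.int(k, n, replace = TRUE, prob = ctab$weight)
  country <- ctab$country[ci]

  # ---- reported sleep ------------------------------------------------------
  latent <- sleep_trend(cfg, age) +
    ifelse(gender == "woman", +cfg$gender_offset / 2, -cfg$gender_offset / 2) +
    ctab$intercept[ci] + ctab$cluster_shift[ci] +
    stats::rnorm(n, 0, cfg$residual_sd)
  sleep <- if (cfg$round_sleep) {
    clamp(round(latent), cfg$sleep_support[1], cfg$sleep_support[2])
  } else latent
  if (cfg$long_outlier_rate > 0) {
    is_out <- stats::runif(n) < cfg$long_outlier_rate
    n_out <- sum(is_out)
    if (n_out > 0) sleep[is_out] <- sample(c(11, 12), n_out, replace = TRUE)
  }

  # ---- latent skills -------------------------------------------------------
  grp <- if (length(cfg$true_changepoints) == 2) {
    assign_age_groups(age, cfg$true_changepoints)
  } else {
    # skill-link groups are only meaningful for the canonical 3-phase world
    factor(rep("middle", n), levels = c("young", "middle", "older"))
  }
  b1 <- cfg$skill_link_lin[as.character(grp)]
  b2 <- cfg$skill_link_quad[as.character(grp)]
  s7 <- sleep - 7
  nav_skill <- clamp(0.5 + b1 * s7 + b2 * s7^2 +
                       stats::rnorm(n, 0, cfg$skill_sd), 0.02, 0.98)
  motor_skill <- clamp(stats::rnorm(n, 0.6, 0.15), 0.05, 0.95)

  records <- data.frame(
    participant_id = sprintf("P%07d", seq_len(n)),
    age = as.integer(age),
    gender = gender,
    education = education,
    home_env = home_env,
    commute = commute,
    country = country,
    sleep_hours = as.numeric(sleep),
    stringsAsFactors = FALSE
  )

  truth <- list(
    true_changepoints = cfg$true_changepoints,
    phase_slopes = cfg$phase_slopes,
    intercept_at_min = cfg$intercept_at_min,
    gender_offset = cfg$gender_offset,
    residual_sd = cfg$residual_sd,
    countries = ctab,
    cluster_shifts = shifts,
    skill_link = list(lin = cfg$skill_link_lin, quad = cfg$skill_link_quad,
                      peak_hours = 7),
    participants = data.frame(
      participant_id = records$participant_id,
      nav_skill = nav_skill,
      motor_skill = motor_skill,
      age_group = as.character(grp),
      stringsAsFactors = FALSE
    )
  )
  list(records = records, truth = truth)
}

#' Write / read a cohort table as CSV
#'
#' Column order is participant_id, age, gender, education, home_env, commute,
#' country, sleep_hours; UTF-8, header required.
#'
#' @param records cohort data.frame.
#' @param path file path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort_csv <- function(records, path) {
  cols <- c("participant_id", "age", "gender", "education", "home_env",
            "commute", "country", "sleep_hours")
  stopifnot(all(cols %in% names(records)))
  utils::write.csv(records[cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Serialize ground truth to JSON next to a generated dataset
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
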