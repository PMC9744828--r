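#' Inclusion filter configuration
#'
#' @param max_age maximum age retained, inclusive (default 70; older
#'   participants are removed because of self-selection bias).
#' @param sleep_range inclusive retained range of reported sleep hours,
#'   default `c(5, 10)` (exactly 5 h and exactly 10 h are kept).
#' @param min_country_n minimum number of remaining participants a country
#'   needs to be retained (default 500); applied after the row filters.
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_age = 70, sleep_range = c(5, 10),
                          min_country_n = 500) {
  if (length(sleep_range) != 2 || diff(sleep_range) < 0) {
    stop("sleep_range must be two ordered bounds", call. = FALSE)
  }
  if (min_country_n < 1) stop("min_country_n must be >= 1", call. = FALSE)
  structure(list(max_age = max_age, sleep_range = as.numeric(sleep_range),
                 min_country_n = as.integer(min_country_n)),
            class = "filter_config")
}

#' Apply the cohort inclusion filters
#'
#' Removes, in this order: participants older than `max_age`; reported sleep
#' below / above the retained range; then, on what remains, all participants
#' from countries with fewer than `min_country_n` players. Each removed row
#' is counted under exactly one reason (age first, then sleep_low, then
#' sleep_high).
#'
#' @param records cohort data.frame.
#' @param config a [filter_config()].
#' @return list with `records` (kept rows) and `report` (named counts:
#'   `age`, `sleep_low`, `sleep_high`, `country`, `kept`, plus
#'   `n_countries_kept`).
#' @export
apply_inclusion_filters <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  age_bad <- records$age > config$max_age
  sleep_low <- !age_bad & records$sleep_hours < config$sleep_range[1]
  sleep_high <- !age_bad & records$sleep_hours > config$sleep_range[2]
  keep <- !(age_bad | sleep_low | sleep_high)
  kept <- records[keep, , drop = FALSE]
  country_n <- table(kept$country)
  small <- names(country_n)[country_n < config$min_country_n]
  country_bad <- kept$country %in% small
  kept <- kept[!country_bad, , drop = FALSE]
  rownames(kept) <- NULL
  list(
    records = kept,
    report = list(
      age = sum(age_bad),
      sleep_low = sum(sleep_low),
      sleep_high = sum(sleep_high),
      country = sum(country_bad),
      kept = nrow(kept),
      n_countries_kept = length(unique(kept$country))
    )
  )
}

#' Mean reported sleep within fixed-width age windows
#'
#' Non-overlapping windows of `window` years starting at the youngest age
#' (with 3-year windows and ages 19-70: 19-21, 22-24, ..., 67-69, 70).
#' Reports per window the bin center, mean sleep, number of records and the
#' 95% CI half-width (1.96 x SE). Optionally stratified by a factor column.
#'
#' @param records filtered cohort data.frame.
#' @param window window width in years, default 3.
#' @param group_by optional name of a column to stratify by (e.g. "gender").
#' @return data.frame with columns `group` (if stratified), `age_lo`,
#'   `age_hi`, `center`, `n`, `mean_sleep`, `se`, `ci_half`. Empty windows
#'   are omitted with a warning.
#' @export
bin_age_curve <- function(records, window = 3, group_by = NULL) {
  if (nrow(records) == 0) stop("no records to bin", call. = FALSE)
  a0 <- min(records$age)
  bin <- (records$age - a0) %/% window
  grp <- if (is.null(group_by)) rep("all", nrow(records)) else {
    as.character(records[[group_by]])
  }
  dt <- data.table::data.table(bin = bin, grp = grp,
                               sleep = records$sleep_hours, age = records$age)
  agg <- dt[, .(n = .N, mean_sleep = mean(sleep),
                se = stats::sd(sleep) / sqrt(.N)),
            by = .(grp, bin)]
  data.table::setorder(agg, grp, bin)
  all_bins <- seq(0, max(bin))
  missing_bins <- setdiff(all_bins, unique(agg$bin))
  if (length(missing_bins) > 0) {
    warning("empty age windows omitted: ",
            paste(a0 + missing_bins * window, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    group = agg$grp,
    age_lo = a0 + agg$bin * window,
    age_hi = a0 + agg$bin * window + window - 1,
    n = agg$n,
    mean_sleep = agg$mean_sleep,
    se = agg$se,
    stringsAsFactors = FALSE
  )
  out$age_hi <- pmin(out$age_hi, max(records$age))
  out$center <- (out$age_lo + out$age_hi) / 2
  out$ci_half <- 1.96 * out$se
  if (is.null(group_by)) out$group <- NULL
  out
}

#' Per-integer-age mean sleep signal
#'
#' One mean per integer year of age over the filtered records; the input the
#' change-point stage segments. Every age in the observed range must be
#' populated.
#'
#' @param records filtered cohort data.frame.
#' @return a [as_signal()] object with ages as positions.
#' @export
per_age_mean_signal <- function(records) {
  if (nrow(records) == 0) stop("no records", call. = FALSE)
  ages <- sort(unique(records$age))
  full <- seq(min(ages), max(ages))
  if (!identical(as.integer(ages), as.integer(full))) {
    stop("ages with no records inside the range: ",
         paste(setdiff(full, ages), collapse = ", "), call. = FALSE)
  }
  m <- tapply(records$sleep_hours, records$age, mean)
  as_signal(as.numeric(names(m)), as.numeric(m))
}

#' Hedges' g standardized mean difference
#'
#' Pooled-SD standardized difference of means with the small-sample bias
#' correction `J = 1 - 3 / (4 (n1 + n2) - 9)`, and a normal-approximation
#' 95% CI with `SE^2 = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`. Groups
#' may be given as raw value vectors or as `list(mean =, sd =, n =)`
#' summaries; both routes agree to machine precision.
#'
#' @param group_a,group_b numeric vectors, or lists with elements `mean`,
#'   `sd`, `n`.
#' @return an `effect_size`: `g`, `ci_low`, `ci_high`, `n1`, `n2`.
#'   `hedges_g(a, b)` equals `-hedges_g(b, a)`.
#' @export
hedges_g <- function(group_a, group_b) {
  summarize <- function(g) {
    if (is.list(g)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(g)))
      list(m = g$mean, s = g$sd, n = as.numeric(g$n))  # avoid int overflow
    } else {
      if (length(g) < 2) stop("raw groups need n >= 2", call. = FALSE)
      list(m = mean(g), s = stats::sd(g), n = as.numeric(length(g)))
    }
  }
  a <- summarize(group_a)
  b <- summarize(group_b)
  if (a$n < 2 || b$n < 2) stop("both groups need n >= 2", call. = FALSE)
  if (a$s < 0 || b$s < 0) stop("sds must be >= 0", call. = FALSE)
  n <- a$n + b$n
  s_pooled <- sqrt(((a$n - 1) * a$s^2 + (b$n - 1) * b$s^2) / (n - 2))
  if (s_pooled <= 0) {
    stop("zero pooled SD: effect size undefined", call. = FALSE)
  }
  j <- 1 - 3 / (4 * n - 9)
  g <- j * (a$m - b$m) / s_pooled
  se <- sqrt(n / (a$n * b$n) + g^2 / (2 * n))
  structure(list(g = g, ci_low = g - 1.96 * se, ci_high = g + 1.96 * se,
                 n1 = a$n, n2 = b$n),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f, 95%% CI [%.3f, %.3f] (n1 = %d, n2 = %d)\n",
              x$g, x$ci_low, x$ci_high, x$n1, x$n2))
  invisible(x)
}

#' Short- and long-sleeper proportions by gender and age group
#'
#' Short sleepers report exactly 5 h; long sleepers 9 or 10 h. Age groups
#' are the three life-course phases implied by the change points (see
#' [assign_age_groups()]).
#'
#' @param records filtered cohort data.frame.
#' @param changepoints the two detected change-point ages, default
#'   `c(33, 53)`.
#' @return data.frame with one row per gender x age-group cell: `gender`,
#'   `age_group`, `n`, `p_short`, `p_long`, `p_mid`. Empty cells are flagged
#'   with `NA` proportions.
#' @export
sleeper_proportions <- function(records, changepoints = c(33, 53)) {
  grp <- assign_age_groups(records$age, changepoints)
  cells <- expand.grid(gender = sort(unique(records$gender)),
                       age_group = levels(grp), stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- records$gender == cells$gender[i] & grp == cells$age_group[i]
    n <- sum(sel)
    if (n == 0) {
      data.frame(cells[i, ], n = 0L, p_short = NA_real_, p_long = NA_real_,
                 p_mid = NA_real_)
    } else {
      s <- records$sleep_hours[sel]
      data.frame(cells[i, ], n = n,
                 p_short = mean(s == 5),
                 p_long = mean(s >= 9),
                 p_mid = mean(s > 5 & s < 9))
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mixed model of reported sleep with country random intercepts
#'
#' Fits, by maximum likelihood,
#' `sleep ~ age_c * (gender + education + home_env + commute) + age_c^2 +
#' (1 | country)` where `age_c` is age centered at its mean (reducing the
#' collinearity of age and age squared). Treatment coding with reference
#' levels man / secondary / non-city / <30min. Returns Wald CIs for fixed
#' effects and the per-country conditional modes (BLUPs of the random
#' intercepts: each country's deviation from the population-level
#' prediction).
#'
#' @param records filtered cohort data.frame with >= 2 countries.
#' @return a `sleep_lmm_summary`: `coefficients` (data.frame term, estimate,
#'   se, ci_low, ci_high), `conditional_modes` (data.frame country, mode),
#'   `varcomp` (country intercept SD, residual SD), `age_center`, and the
#'   fitted `model`.
#' @export
fit_sleep_lmm <- function(records) {
  if (length(unique(records$country)) < 2) {
    stop("need at least 2 countries for a random-intercept model",
         call. = FALSE)
  }
  d <- records
  d$gender <- stats::relevel(factor(d$gender), ref = "man")
  d$education <- stats::relevel(factor(d$education), ref = "secondary")
  d$home_env <- stats::relevel(factor(d$home_env), ref = "non-city")
  d$commute <- stats::relevel(factor(d$commute), ref = "<30min")
  for (v in c("gender", "education", "home_env", "commute")) {
    if (nlevels(droplevels(d[[v]])) < 2) {
      stop("factor '", v, "' has a single level: singular design",
           call. = FALSE)
    }
  }
  age_center <- mean(d$age)
  d$age_c <- d$age - age_center
  fit <- lme4::lmer(
    sleep_hours ~ age_c * (gender + education + home_env + commute) +
      I(age_c^2) + (1 | country),
    data = d, REML = FALSE,
    control = lme4::lmerControl(calc.derivs = FALSE))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  coefs <- data.frame(term = names(fe), estimate = as.numeric(fe),
                      se = se,
                      ci_low = as.numeric(fe) - 1.96 * se,
                      ci_high = as.numeric(fe) + 1.96 * se,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  re <- lme4::ranef(fit)$country
  modes <- data.frame(country = rownames(re), mode = re[[1]],
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- stats::setNames(vc$sdcor, vc$grp)
  structure(list(coefficients = coefs, conditional_modes = modes,
                 varcomp = varcomp, age_center = age_center, model = fit),
            class = "sleep_lmm_summary")
}

#' @export
print.sleep_lmm_summary <- function(x, ...) {
  cat("Linear mixed model of reported sleep (ML, country random intercept)\n")
  cat(sprintf("  %d fixed effects, %d countries; SD(country) = %.3f h, ",
              nrow(x$coefficients), nrow(x$conditional_modes),
              x$varcomp[["country"]]))
  cat(sprintf("SD(residual) = %.3f h\n", x$varcomp[["Residual"]]))
  invisible(x)
}

#' Correlation of country conditional modes with raw country means
#'
#' @param records filtered cohort data.frame.
#' @param modes data.frame `country`, `mode` (from [fit_sleep_lmm()]).
#' @return list `r` (Pearson correlation), `p`, `n_countries`.
#' @export
conditional_mode_vs_raw <- function(records, modes) {
  raw <- tapply(records$sleep_hours, records$country, mean)
  common <- intersect(names(raw), modes$country)
  if (length(common) < 3) stop("need >= 3 countries", call. = FALSE)
  x <- as.numeric(raw[common])
  y <- modes$mode[match(common, modes$country)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n_countries = length(common))
}

#' Quadratic sleep-performance models per age group
#'
#' For each outcome (WF and TP) fits, by ordinary least squares,
#' `performance ~ age_group * (sleep + sleep^2) + education + home_env +
#' commute` with treatment coding (reference group: young). Reports the
#' group-specific linear and quadratic sleep coefficients with Wald CIs and
#' the sleep duration maximizing each group's fitted parabola,
#' `-b1_g / (2 b2_g)`, with a delta-method CI.
#'
#' @param scores data.frame from [compute_tp_wf()].
#' @param records filtered cohort data.frame.
#' @param changepoints the two change-point ages defining the groups.
#' @return a `performance_model_summary`: per outcome a list with
#'   `coefficients` (full OLS table), `group_terms` (per age group: linear
#'   and quadratic sleep coefficients with CIs) and `peaks` (per age group:
#'   peak sleep hours, se, ci_low, ci_high).
#' @export
fit_performance_model <- function(scores, records, changepoints = c(33, 53)) {
  d <- merge(records, scores[!is.na(scores$wf),
                             c("participant_id", "tp", "wf")],
             by = "participant_id")
  if (nrow(d) < 10) stop("too few scored participants", call. = FALSE)
  d$age_group <- assign_age_groups(d$age, changepoints)
  d$education <- stats::relevel(factor(d$education), ref = "secondary")
  d$home_env <- stats::relevel(factor(d$home_env), ref = "non-city")
  d$commute <- stats::relevel(factor(d$commute), ref = "<30min")
  d$sleep <- d$sleep_hours
  for (g in levels(d$age_group)) {
    ss <- d$sleep[d$age_group == g]
    if (length(unique(ss)) < 2) {
      stop("age group '", g, "' has < 2 distinct sleep values", call. = FALSE)
    }
  }
  fit_one <- function(outcome) {
    f <- stats::as.formula(paste(
      outcome, "~ age_group * (sleep + I(sleep^2)) + education + home_env",
      "+ commute"))
    fit <- stats::lm(f, data = d)
    ct <- summary(fit)$coefficients
    V <- stats::vcov(fit)
    coefs <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                        ci_low = ct[, 1] - 1.96 * ct[, 2],
                        ci_high = ct[, 1] + 1.96 * ct[, 2],
                        stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    groups <- levels(d$age_group)
    res <- lapply(groups, function(g) {
      lin_terms <- "sleep"
      quad_terms <- "I(sleep^2)"
      if (g != groups[1]) {
        lin_terms <- c(lin_terms, paste0("age_group", g, ":sleep"))
        quad_terms <- c(quad_terms, paste0("age_group", g, ":I(sleep^2)"))
      }
      cn <- rownames(ct)
      wl <- as.numeric(cn %in% lin_terms)
      wq <- as.numeric(cn %in% quad_terms)
      b1 <- sum(wl * ct[, 1]); b2 <- sum(wq * ct[, 1])
      v11 <- drop(t(wl) %*% V %*% wl)
      v22 <- drop(t(wq) %*% V %*% wq)
      v12 <- drop(t(wl) %*% V %*% wq)
      peak <- -b1 / (2 * b2)
      # delta method on f(b1, b2) = -b1 / (2 b2)
      g1 <- -1 / (2 * b2)
      g2 <- b1 / (2 * b2^2)
      peak_se <- sqrt(g1^2 * v11 + 2 * g1 * g2 * v12 + g2^2 * v22)
      list(group = g,
           lin = b1, lin_se = sqrt(v11),
           lin_ci = b1 + c(-1.96, 1.96) * sqrt(v11),
           quad = b2, quad_se = sqrt(v22),
           quad_ci = b2 + c(-1.96, 1.96) * sqrt(v22),
           peak = peak, peak_se = peak_se,
           peak_ci = peak + c(-1.96, 1.96) * peak_se)
    })
    names(res) <- groups
    list(coefficients = coefs, group_terms = res, model = fit)
  }
  structure(list(wf = fit_one("wf"), tp = fit_one("tp"),
                 changepoints = changepoints, n = nrow(d)),
            class = "performance_model_summary")
}

#' @export
print.performance_model_summary <- function(x, ...) {
  cat("Quadratic sleep-performance models (OLS, n =", x$n, ")\n")
  for (oc in c("wf", "tp")) {
    cat(" ", toupper(oc), "per-group sleep terms:\n")
    for (g in x[[oc]]$group_terms) {
      cat(sprintf("    %-6s b1 = %+.3f  b2 = %+.4f  peak = %.2f h [%.2f, %.2f]\n",
                  g$group, g$lin, g$quad, g$peak, g$peak_ci[1], g$peak_ci[2]))
    }
  }
  invisible(x)
}
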