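#' Packaged supra-national country cluster table
#'
#' Returns the packaged table of countries with their historical-economic
#' (Maddison-style, 7 groups) and cultural (11 groups) supra-national
#' cluster labels and a WEIRD (Western, Educated, Industrialized, Rich,
#' Democratic) flag. England is carried under the United Kingdom's ISO code
#' `GB`. The WEIRD flag marks the Western Europe and Western Offshoot
#' clusters; see the methods vignette for the approximation involved.
#'
#' @return data.frame: `country` (name), `code` (ISO-3166 alpha-2),
#'   `maddison_cluster`, `cultural_cluster`, `weird` (logical).
#' @export
country_clusters <- function() {
  path <- system.file("extdata", "country_clusters.csv",
                      package = "sleepcourse", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$weird <- as.logical(d$weird)
  d
}

#' Read a country metadata CSV
#'
#' Expected columns: `country`, `abs_latitude`, `gdp_per_capita`,
#' `maddison_cluster`, `cultural_cluster`, `weird`.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_country_metadata <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "abs_latitude", "gdp_per_capita",
            "maddison_cluster", "cultural_cluster", "weird")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("country metadata is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(d$abs_latitude < 0 | d$abs_latitude > 90)) {
    stop("abs_latitude must be within [0, 90]", call. = FALSE)
  }
  d$weird <- as.logical(d$weird)
  d
}

#' Per-country summaries for the geographic stage
#'
#' @param records filtered cohort data.frame.
#' @param metadata country metadata (columns `country`, `abs_latitude`,
#'   `gdp_per_capita`, `maddison_cluster`, `cultural_cluster`, `weird`).
#' @param modes optional conditional modes from [fit_sleep_lmm()].
#' @return data.frame, one row per country present in `records`: `country`,
#'   `n`, `mean_sleep`, `conditional_mode` (NA if `modes` not given) and the
#'   metadata columns.
#' @export
country_summaries <- function(records, metadata, modes = NULL) {
  dt <- data.table::as.data.table(records)
  agg <- dt[, .(n = .N, mean_sleep = mean(sleep_hours)), by = country]
  data.table::setDF(agg)
  out <- merge(agg, metadata, by = "country", all.x = TRUE)
  if (anyNA(out$abs_latitude)) {
    stop("metadata missing for countries: ",
         paste(out$country[is.na(out$abs_latitude)], collapse = ", "),
         call. = FALSE)
  }
  out$conditional_mode <- if (is.null(modes)) NA_real_ else {
    modes$mode[match(out$country, modes$country)]
  }
  out[order(out$country), ]
}

# Build the participant-level design for the cluster ANOVA and return the
# partial F for the cluster factor: sleep ~ age + gender + cluster vs the
# model without cluster.
cluster_f_from_design <- function(y, age, gender_num, cluster) {
  n <- length(y)
  x_red <- cbind(1, age, gender_num)
  fit_red <- stats::lm.fit(x_red, y)
  rss_red <- sum(fit_red$residuals^2)
  cl <- factor(cluster)
  k <- nlevels(cl)
  if (k < 2) stop("need >= 2 clusters", call. = FALSE)
  x_full <- cbind(x_red, stats::model.matrix(~ cl)[, -1, drop = FALSE])
  fit_full <- stats::lm.fit(x_full, y)
  rss_full <- sum(fit_full$residuals^2)
  df1 <- k - 1
  df2 <- n - ncol(x_full)
  f <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  list(f = f, df1 = df1, df2 = df2)
}

#' ANOVA F for supra-national clusters
#'
#' F statistic of the cluster factor in the fixed-effects linear model
#' `sleep ~ age + gender + cluster` (age linear), computed as the partial F
#' of adding the cluster dummies; degrees of freedom (k - 1, n - p) with p
#' the number of columns of the full design.
#'
#' @param records filtered cohort data.frame.
#' @param cluster_map named character vector or data.frame
#'   (`country`, `cluster`) mapping every country in `records` to a cluster.
#' @return list `f`, `df1`, `df2`.
#' @export
cluster_anova_f <- function(records, cluster_map) {
  map <- as_cluster_map(cluster_map)
  cl <- unname(map[records$country])
  if (anyNA(cl)) {
    stop("unmapped countries: ",
         paste(unique(records$country[is.na(cl)]), collapse = ", "),
         call. = FALSE)
  }
  cluster_f_from_design(records$sleep_hours, records$age,
                        as.numeric(records$gender == "woman"), cl)
}

as_cluster_map <- function(cluster_map) {
  if (is.data.frame(cluster_map)) {
    stopifnot(all(c("country", "cluster") %in% names(cluster_map)))
    stats::setNames(as.character(cluster_map$cluster), cluster_map$country)
  } else if (!is.null(names(cluster_map))) {
    cluster_map
  } else {
    stop("cluster_map must be a named vector or a country/cluster data frame",
         call. = FALSE)
  }
}

#' Country-label permutation null for the cluster ANOVA F
#'
#' Shuffles the country-to-cluster assignment across countries (participants
#' keep their country, so all within-country structure is preserved) and
#' recomputes the cluster F per shuffle. The empirical p-value is
#' `(1 + #\{null F >= observed F\}) / (n_shuffles + 1)`, so its floor is
#' `1 / (n_shuffles + 1)`. With `level = "participant"` the cluster labels
#' are shuffled across participants instead (a much weaker null that ignores
#' within-country clustering).
#'
#' @inheritParams cluster_anova_f
#' @param n_shuffles number of label shuffles, default 100.
#' @param seed RNG seed for reproducible shuffles.
#' @param level `"country"` (default) or `"participant"`.
#' @return a `permutation_outcome`: `observed_f`, `df1`, `df2`, `null_f`
#'   (length `n_shuffles`), `p`, `n_shuffles`, `seed`, `level`.
#' @export
permutation_null <- function(records, cluster_map, n_shuffles = 100,
                             seed = NULL, level = c("country", "participant")) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1", call. = FALSE)
  level <- match.arg(level)
  map <- as_cluster_map(cluster_map)
  countries <- unique(records$country)
  if (!all(countries %in% names(map))) {
    stop("unmapped countries in records", call. = FALSE)
  }
  map <- map[countries]
  y <- records$sleep_hours
  age <- records$age
  gn <- as.numeric(records$gender == "woman")
  obs <- cluster_f_from_design(y, age, gn, unname(map[records$country]))
  if (!is.null(seed)) set.seed(seed)
  null_f <- vapply(seq_len(n_shuffles), function(i) {
    cl <- if (level == "country") {
      shuffled <- stats::setNames(sample(unname(map)), names(map))
      unname(shuffled[records$country])
    } else {
      sample(unname(map[records$country]))
    }
    cluster_f_from_design(y, age, gn, cl)$f
  }, numeric(1))
  p <- (1 + sum(null_f >= obs$f)) / (n_shuffles + 1)
  structure(list(observed_f = obs$f, df1 = obs$df1, df2 = obs$df2,
                 null_f = null_f, p = p, n_shuffles = n_shuffles,
                 seed = seed, level = level),
            class = "permutation_outcome")
}

#' @export
print.permutation_outcome <- function(x, ...) {
  cat(sprintf("Cluster ANOVA permutation test (%s-level shuffle)\n", x$level))
  cat(sprintf("  observed F(%d, %d) = %.2f; null mean F = %.2f; p = %.4f (%d shuffles)\n",
              x$df1, x$df2, x$observed_f, mean(x$null_f), x$p, x$n_shuffles))
  invisible(x)
}

#' Correlation of country mean sleep with absolute latitude
#'
#' @param summaries country summaries with columns `mean_sleep` and
#'   `abs_latitude` (>= 3 countries).
#' @return list `r`, `p`, `n_countries`.
#' @export
latitude_correlation <- function(summaries) {
  if (nrow(summaries) < 3) stop("need >= 3 countries", call. = FALSE)
  x <- summaries$abs_latitude
  y <- summaries$mean_sleep
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n_countries = nrow(summaries))
}

#' Country-level regression of sleep on GDP per capita and latitude
#'
#' Ordinary least squares at the country level, with either the raw country
#' mean sleep or the mixed-model conditional mode as response, and optional
#' WEIRD-status adjustment. t statistics are reported with the residual
#' degrees of freedom `n - p`.
#'
#' @param summaries country summaries (see [country_summaries()]).
#' @param response `"mean_sleep"` or `"conditional_mode"`.
#' @param include_weird add the WEIRD flag as a third predictor.
#' @return data.frame: `term`, `estimate`, `se`, `t`, `df`, `p`, `ci_low`,
#'   `ci_high`.
#' @export
gdp_latitude_regression <- function(summaries,
                                    response = c("mean_sleep",
                                                 "conditional_mode"),
                                    include_weird = FALSE) {
  response <- match.arg(response)
  d <- summaries
  d$.y <- d[[response]]
  if (anyNA(d$.y)) stop("response contains NA", call. = FALSE)
  f <- if (include_weird) {
    .y ~ gdp_per_capita + abs_latitude + weird
  } else {
    .y ~ gdp_per_capita + abs_latitude
  }
  p <- if (include_weird) 4 else 3
  if (nrow(d) <= p) stop("need more countries than predictors + 1", call. = FALSE)
  fit <- stats::lm(f, data = d)
  if (any(!is.finite(stats::coef(fit)))) {
    stop("collinear predictors: singular fit", call. = FALSE)
  }
  ct <- summary(fit)$coefficients
  out <- data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                    t = ct[, 3], df = fit$df.residual, p = ct[, 4],
                    ci_low = ct[, 1] - 1.96 * ct[, 2],
                    ci_high = ct[, 1] + 1.96 * ct[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Change points within cohort subgroups
#'
#' Splits the cohort by a factor column (e.g. gender or a WEIRD flag joined
#' onto the records), builds each subgroup's per-integer-age mean signal and
#' segments it with the default penalty.
#'
#' @param records filtered cohort data.frame.
#' @param split name of the column to split by.
#' @param beta penalty per change point, default 0.02.
#' @return named list (one entry per subgroup level) of
#'   `segmentation_result` objects.
#' @export
subgroup_changepoints <- function(records, split, beta = 0.02) {
  stopifnot(split %in% names(records))
  groups <- split(records, records[[split]])
  lapply(groups, function(g) {
    optimal_segmentation(per_age_mean_signal(g), beta)
  })
}
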