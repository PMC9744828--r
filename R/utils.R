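# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Population z-score
#'
#' Standardizes a vector to mean 0 and *population* standard deviation 1
#' (denominator n, not n - 1). The worked scoring examples in the package
#' documentation use this convention, so the scored set satisfies
#' `mean == 0` and `sqrt(mean((x - mean(x))^2)) == 1` exactly.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return numeric vector of the same length.
#' @keywords internal
zscore_pop <- function(x) {
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s <= 0 || !is.finite(s)) {
    stop("cannot z-score a constant (zero-variance) vector", call. = FALSE)
  }
  (x - m) / s
}

#' Assign participants to the three life-course age groups
#'
#' Given two change points (ages, by the detection convention: a change point
#' at age `a` starts a new segment at `a`), participants are labelled by the
#' conventional inclusive phase labels: with change points 33 and 53 the
#' groups are 19-33, 34-53 and 54+ (half-open intervals
#' `[min, cp1 + 1)`, `[cp1 + 1, cp2 + 1)`, `[cp2 + 1, Inf)`).
#'
#' @param age integer vector of ages in years.
#' @param changepoints two strictly increasing change-point ages.
#' @return factor with levels `"young"`, `"middle"`, `"older"`.
#' @export
assign_age_groups <- function(age, changepoints = c(33, 53)) {
  stopifnot(length(changepoints) == 2, diff(changepoints) > 0)
  cut(age,
      breaks = c(-Inf, changepoints[1] + 1, changepoints[2] + 1, Inf),
      labels = c("young", "middle", "older"),
      right = FALSE)
}

# consistent integer sub-seed derived from a user seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}
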