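#' Construct a 1-D signal for change-point analysis
#'
#' A signal is an ordered set of (position, value) pairs, typically the mean
#' reported sleep duration per integer year of age. Positions must be
#' strictly increasing and all values finite.
#'
#' @param positions numeric, strictly increasing (e.g. ages in years).
#' @param values numeric measurements, same length as `positions`.
#' @return an object of class `"sleep_signal"`.
#' @export
as_signal <- function(positions, values) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) != length(values)) {
    stop("positions and values must have equal length", call. = FALSE)
  }
  if (length(positions) < 2) {
    stop("a signal needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(positions)) || any(!is.finite(values))) {
    stop("signal contains non-finite entries", call. = FALSE)
  }
  if (any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  structure(list(positions = positions, values = values),
            class = "sleep_signal")
}

#' @export
print.sleep_signal <- function(x, ...) {
  cat(sprintf("<signal: %d points, positions %g..%g>\n",
              length(x$positions), min(x$positions), max(x$positions)))
  invisible(x)
}

as_signal_like <- function(signal) {
  if (inherits(signal, "sleep_signal")) return(signal)
  if (is.data.frame(signal) && ncol(signal) >= 2) {
    return(as_signal(signal[[1]], signal[[2]]))
  }
  stop("expected a sleep_signal or a two-column data frame", call. = FALSE)
}

#' Residual sum of squares of a least-squares line over a signal slice
#'
#' Fits a straight line by exact least squares through the points
#' `positions[start:end]`, `values[start:end]` (1-based, inclusive) and
#' returns the sum of squared residuals. Slices of one or two points fit
#' exactly (SSE = 0), as does any collinear slice.
#'
#' @param signal a `sleep_signal`.
#' @param start,end 1-based inclusive slice bounds, `start <= end`.
#' @return non-negative scalar, in squared signal units.
#' @export
segment_sse <- function(signal, start, end) {
  signal <- as_signal_like(signal)
  n <- length(signal$positions)
  if (start < 1 || end > n || start > end) {
    stop("invalid slice [", start, ", ", end, "]", call. = FALSE)
  }
  x <- signal$positions[start:end]
  y <- signal$values[start:end]
  m <- length(x)
  if (m <= 2) return(0)
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  sxy <- sum(xc * yc)
  syy <- sum(yc^2)
  max(0, syy - sxy^2 / sxx)
}

# Cost matrix of all contiguous slices: cost[i, j] = SSE of slice i..j.
# Signals here are short (~52 points for ages 19-70), so the O(n^2) table
# with an O(n) exact centered computation per entry is both fast and
# numerically clean.
segment_cost_matrix <- function(signal) {
  n <- length(signal$positions)
  cost <- matrix(0, n, n)
  for (i in seq_len(n - 2)) {
    x <- signal$positions
    y <- signal$values
    for (j in (i + 2):n) {
      xs <- x[i:j]; ys <- y[i:j]
      xc <- xs - mean(xs); yc <- ys - mean(ys)
      sxx <- sum(xc^2)
      cost[i, j] <- max(0, sum(yc^2) - sum(xc * yc)^2 / sxx)
    }
  }
  cost
}

# Compare two candidate segmentations:
# deviation first, then fewer change points, then lexicographically smaller
# change-point index list. Returns TRUE if `a` is strictly better than `b`.
# `tol` guards against floating-point ties in the deviation.
better_solution <- function(dev_a, cps_a, dev_b, cps_b, tol = 1e-12) {
  if (dev_a < dev_b - tol) return(TRUE)
  if (dev_a > dev_b + tol) return(FALSE)
  ka <- length(cps_a); kb <- length(cps_b)
  if (ka != kb) return(ka < kb)
  if (ka == 0L) return(FALSE)
  d <- cps_a - cps_b
  nz <- which(d != 0)
  if (length(nz) == 0L) return(FALSE)
  d[nz[1]] < 0
}

build_result <- function(signal, cp_idx, beta, cost = NULL) {
  n <- length(signal$positions)
  bounds <- c(1L, cp_idx, n + 1L)
  segs <- vector("list", length(bounds) - 1L)
  total_sse <- 0
  for (s in seq_along(segs)) {
    i <- bounds[s]; j <- bounds[s + 1L] - 1L
    x <- signal$positions[i:j]; y <- signal$values[i:j]
    if (length(x) == 1L) {
      slope <- 0; intercept <- y
      sse <- 0
    } else {
      xc <- x - mean(x)
      sxx <- sum(xc^2)
      slope <- sum(xc * (y - mean(y))) / sxx
      intercept <- mean(y) - slope * mean(x)
      sse <- if (!is.null(cost)) cost[i, j] else segment_sse(signal, i, j)
    }
    segs[[s]] <- list(start_index = i, end_index = j + 1L,  # half-open
                      slope = slope, intercept = intercept, sse = sse)
    total_sse <- total_sse + sse
  }
  structure(list(
    changepoints = signal$positions[cp_idx],
    changepoint_indices = cp_idx,
    segments = segs,
    total_sse = total_sse,
    penalty_beta = beta,
    deviation = total_sse + beta * length(cp_idx)
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Penalized piecewise-linear segmentation (beta = %g)\n",
              x$penalty_beta))
  if (length(x$changepoints) == 0) {
    cat("  change points: none\n")
  } else {
    cat("  change points at positions:",
        paste(format(x$changepoints), collapse = ", "), "\n")
    cat("  (a change point at position a starts the segment [a, ...))\n")
  }
  cat(sprintf("  total SSE = %.6g, deviation = %.6g\n",
              x$total_sse, x$deviation))
  invisible(x)
}

#' Exact penalized piecewise-linear segmentation
#'
#' Minimizes the penalized deviation
#' \deqn{D_K = \sum_{j} \mathrm{SSE}_j + \beta K}
#' over all numbers K and placements of change points, where each segment is
#' fit by its own independent least-squares line (discontinuities allowed at
#' the breaks). Solved exactly by optimal partitioning (dynamic programming
#' over precomputed segment costs); the result is guaranteed to equal
#' exhaustive enumeration over all interior division-point subsets.
#'
#' A change point at position `a` means the signal is split into segments
#' `[..., a)` and `[a, ...)`: the reported position is the first sample of
#' the new segment.
#'
#' Ties in deviation are broken deterministically: fewer change points first,
#' then the lexicographically smallest change-point list.
#'
#' @param signal a `sleep_signal` (or two-column data frame position, value).
#' @param beta non-negative penalty per change point, in squared signal
#'   units. Default 0.02, the threshold retained for per-age mean sleep
#'   curves in hours.
#' @return a `segmentation_result`: change-point positions, per-segment fits
#'   (half-open index ranges, slope, intercept, SSE), `total_sse`,
#'   `penalty_beta` and `deviation`.
#' @seealso [brute_force_segmentation()] for the enumeration oracle,
#'   [threshold_sweep()] for stability across penalties.
#' @export
optimal_segmentation <- function(signal, beta = 0.02) {
  signal <- as_signal_like(signal)
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta < 0) {
    stop("beta must be a single non-negative number (Inf allowed)",
         call. = FALSE)
  }
  n <- length(signal$positions)
  cost <- segment_cost_matrix(signal)

  # F[j]: best (deviation, cps) over partitions of 1..j.
  # A boundary before index i (i > 1) is a change point at index i.
  best_dev <- rep(Inf, n + 1L)
  best_cps <- vector("list", n + 1L)
  best_dev[1L] <- 0        # empty prefix
  best_cps[[1L]] <- integer(0)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {  # last segment is i..j
      pen <- if (i > 1L) beta else 0
      dev <- best_dev[i] + cost[i, j] + pen
      if (!is.finite(dev)) next
      cps <- if (i > 1L) c(best_cps[[i]], i) else best_cps[[i]]
      jj <- j + 1L
      if (better_solution(dev, cps, best_dev[jj], best_cps[[jj]])) {
        best_dev[jj] <- dev
        best_cps[[jj]] <- cps
      }
    }
  }
  build_result(signal, as.integer(best_cps[[n + 1L]]), beta, cost)
}

#' Brute-force segmentation oracle
#'
#' Enumerates every subset of interior division points (2^(n-2) candidates)
#' and returns the minimal penalized deviation, with the same deterministic
#' tie-breaking as [optimal_segmentation()]. Intended as an independent test
#' oracle for short signals; refuses signals longer than 16 points.
#'
#' @inheritParams optimal_segmentation
#' @return a `segmentation_result`.
#' @export
brute_force_segmentation <- function(signal, beta = 0.02) {
  signal <- as_signal_like(signal)
  n <- length(signal$positions)
  if (n > 16) {
    stop("brute_force_segmentation is limited to signals of length <= 16",
         call. = FALSE)
  }
  cost <- segment_cost_matrix(signal)
  interior <- if (n >= 2L) 2:n else integer(0)
  best_dev <- Inf
  best_cps <- integer(0)
  m <- length(interior)
  for (mask in 0:(2^m - 1L)) {
    cps <- interior[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    bounds <- c(1L, cps, n + 1L)
    dev <- beta * length(cps)
    for (s in seq_len(length(bounds) - 1L)) {
      dev <- dev + cost[bounds[s], bounds[s + 1L] - 1L]
    }
    if (better_solution(dev, cps, best_dev, best_cps)) {
      best_dev <- dev
      best_cps <- cps
    }
  }
  build_result(signal, as.integer(best_cps), beta, cost)
}

#' Sweep the change-point penalty over a grid of thresholds
#'
#' Runs [optimal_segmentation()] once per threshold value (the threshold is
#' used directly as the per-change-point penalty beta) and summarizes over
#' which contiguous ranges of the grid the detected change-point set is
#' constant. Stability of the set over a wide range is the usual argument
#' for retaining a particular threshold (0.02 by default elsewhere in the
#' package).
#'
#' @param signal a `sleep_signal`.
#' @param t_values positive, sorted vector of thresholds; default the grid
#'   0.005 to 0.09 in steps of 0.001.
#' @return a `threshold_sweep` object: `data.frame` with one row per
#'   threshold (`threshold`, `n_changepoints`, `changepoints` as a
#'   comma-separated string), a `results` list of segmentations, and
#'   `stable_ranges`, one row per run of identical change-point sets.
#' @export
threshold_sweep <- function(signal, t_values = seq(0.005, 0.09, by = 0.001)) {
  signal <- as_signal_like(signal)
  if (length(t_values) == 0) stop("t_values must be non-empty", call. = FALSE)
  if (any(t_values <= 0)) stop("t_values must be positive", call. = FALSE)
  if (is.unsorted(t_values)) stop("t_values must be sorted", call. = FALSE)
  results <- lapply(t_values, function(t) optimal_segmentation(signal, t))
  keys <- vapply(results, function(r) paste(r$changepoints, collapse = ","),
                 character(1))
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  stable <- data.frame(
    t_min = t_values[starts],
    t_max = t_values[ends],
    n_thresholds = runs$lengths,
    changepoints = runs$values,
    stringsAsFactors = FALSE
  )
  structure(list(
    table = data.frame(
      threshold = t_values,
      n_changepoints = vapply(results, function(r) length(r$changepoints), 1L),
      changepoints = keys,
      stringsAsFactors = FALSE
    ),
    results = results,
    stable_ranges = stable
  ), class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("Penalty sweep over", nrow(x$table), "thresholds\n")
  print(x$stable_ranges)
  invisible(x)
}

#' Read a signal from a two-column CSV (position,value)
#' @param path CSV file with a header row.
#' @return a `sleep_signal`.
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  as_signal(d[[1]], d[[2]])
}

#' Serialize a segmentation result to JSON
#' @param result a `segmentation_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segmentation_json <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  out <- list(
    changepoints = result$changepoints,
    penalty_beta = result$penalty_beta,
    total_sse = result$total_sse,
    deviation = result$deviation,
    segments = lapply(result$segments, function(s) {
      s[c("start_index", "end_index", "slope", "intercept", "sse")]
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
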