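#' Path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive trajectory samples, in
#' pixels. A single-sample trajectory has length 0. Invariant to rigid
#' translation and rotation of all samples.
#'
#' @param traj either a data.frame with columns `x` and `y` (rows in time
#'   order) or a two-column numeric matrix.
#' @return non-negative scalar, pixels.
#' @export
trajectory_length <- function(traj) {
  if (is.data.frame(traj)) {
    x <- traj$x; y <- traj$y
  } else if (is.matrix(traj) && ncol(traj) == 2) {
    x <- traj[, 1]; y <- traj[, 2]
  } else {
    stop("traj must be a data.frame with x, y or a 2-column matrix",
         call. = FALSE)
  }
  if (length(x) < 1) stop("trajectory needs at least one sample", call. = FALSE)
  if (length(x) == 1) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

# Per-(participant, level) raw path lengths, keeping only the first attempt
# of each level. An attempt boundary is detected where t_ms fails to
# increase within a (participant, level) block; later attempts are dropped
# with one summary warning.
level_path_lengths <- function(traj) {
  need <- c("participant_id", "level", "t_ms", "x", "y")
  if (!all(need %in% names(traj))) {
    stop("trajectory table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dt <- data.table::as.data.table(traj)
  data.table::setorder(dt, participant_id, level)  # keep row order within block
  dt[, attempt := cumsum(c(TRUE, diff(t_ms) <= 0)),
     by = .(participant_id, level)]
  n_retries <- dt[, any(attempt > 1L), by = .(participant_id, level)][, sum(V1)]
  if (n_retries > 0) {
    warning(n_retries, " (participant, level) retries dropped; ",
            "only first attempts are scored", call. = FALSE)
    dt <- dt[attempt == 1L]
  }
  lens <- dt[, .(raw_length = sum(sqrt(diff(x)^2 + diff(y)^2))),
             by = .(participant_id, level)]
  lens[is.na(raw_length), raw_length := 0]  # single-sample trajectories
  data.table::setDF(lens)
  lens
}

#' Tutorial-normalized level lengths
#'
#' Divides each wayfinding level's raw path length by the sum of the two
#' tutorial path lengths, controlling for device familiarity: a common scale
#' factor on all of a participant's trajectories cancels. Participants with
#' a missing level or a non-positive tutorial sum are excluded with a
#' logged reason.
#'
#' @param raw data.frame with columns `participant_id`, `level`,
#'   `raw_length` (one row per participant x level, first attempts only).
#' @param tutorial_levels,wayfinding_levels integer level ids; defaults 1, 2
#'   and 6, 7, 8, 11.
#' @return list with `lengths` (one row per retained participant:
#'   `participant_id`, `tutorial_sum`, then one `norm_<level>` column per
#'   wayfinding level and one `raw_<level>` per tutorial level) and
#'   `exclusions` (participant_id, reason).
#' @export
normalize_lengths <- function(raw,
                              tutorial_levels = c(1L, 2L),
                              wayfinding_levels = c(6L, 7L, 8L, 11L)) {
  stopifnot(all(c("participant_id", "level", "raw_length") %in% names(raw)))
  dt <- data.table::as.data.table(raw)
  dt <- dt[level %in% c(tutorial_levels, wayfinding_levels)]
  wide <- data.table::dcast(dt, participant_id ~ level,
                            value.var = "raw_length")
  lev_cols <- as.character(c(tutorial_levels, wayfinding_levels))
  missing_cols <- setdiff(lev_cols, names(wide))
  for (mc in missing_cols) wide[, (mc) := NA_real_]
  has_all <- stats::complete.cases(wide[, ..lev_cols])
  tut_sum <- rowSums(wide[, as.character(tutorial_levels), with = FALSE])
  ok <- has_all & !is.na(tut_sum) & tut_sum > 0
  reason <- rep(NA_character_, nrow(wide))
  reason[!has_all] <- "missing_level"
  reason[has_all & !(tut_sum > 0)] <- "zero_tutorial"
  exclusions <- data.frame(participant_id = wide$participant_id[!ok],
                           reason = reason[!ok], stringsAsFactors = FALSE)
  kept <- wide[ok]
  out <- data.frame(participant_id = kept$participant_id,
                    tutorial_sum = tut_sum[ok], stringsAsFactors = FALSE)
  for (tl in tutorial_levels) {
    out[[paste0("raw_", tl)]] <- kept[[as.character(tl)]]
  }
  for (wl in wayfinding_levels) {
    out[[paste0("norm_", wl)]] <- kept[[as.character(wl)]] / out$tutorial_sum
  }
  list(lengths = out, exclusions = exclusions)
}

#' First-principal-component scores of a lengths matrix
#'
#' Projects rows onto the leading eigenvector of the column-centered (not
#' standardized) covariance matrix. The component sign is fixed so that the
#' loadings on the (positively correlated) length columns are non-negative:
#' if the loading sum is negative the component is flipped, and a warning is
#' raised if mixed-sign loadings make the convention only partial.
#'
#' @param mat numeric matrix, participants x levels; >= 2 rows and columns,
#'   all finite.
#' @return list with `scores` (length nrow), `loadings` (length ncol) and
#'   `variance_explained` (fraction in (0, 1]).
#' @export
first_pc_scores <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    stop("need at least 2 rows and 2 columns for a PCA", call. = FALSE)
  }
  if (any(!is.finite(mat))) stop("matrix contains non-finite values", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot <= 0) stop("degenerate (zero-variance) matrix", call. = FALSE)
  loadings <- pc$rotation[, 1]
  scores <- pc$x[, 1]
  if (sum(loadings) < 0) {
    loadings <- -loadings
    scores <- -scores
  }
  if (any(loadings < -1e-8)) {
    warning("mixed-sign loadings: sign convention fixed by loading sum only",
            call. = FALSE)
  }
  list(scores = unname(scores),
       loadings = unname(loadings),
       variance_explained = pc$sdev[1]^2 / tot)
}

#' Compose a performance score from raw length-based PC scores
#'
#' Length-based scores vary opposite to performance, so the raw score is
#' negated (higher = better), shifted so the worst participant sits exactly
#' at 0, and z-scored over the scored population (population SD, so the
#' scored set has mean 0 and population SD 1 exactly).
#'
#' @param raw_scores numeric vector of raw first-PC scores (length >= 2,
#'   non-constant).
#' @return numeric vector of z-scored performance values.
#' @export
compose_performance <- function(raw_scores) {
  if (length(raw_scores) < 2) stop("need at least 2 scores", call. = FALSE)
  flipped <- -raw_scores
  shifted <- flipped - min(flipped)   # worst performance at exactly 0
  zscore_pop(shifted)
}

#' Wayfinding and training performance from raw trajectories
#'
#' End-to-end scoring: first attempts only, per-level path lengths,
#' exclusion of participants with missing levels or a zero tutorial sum,
#' tutorial normalization of the wayfinding levels, first-PC composites and
#' the negate/offset/z-score composition of [compose_performance()].
#' Wayfinding performance (WF) is built from the tutorial-normalized lengths
#' of the four wayfinding levels; training performance (TP) from the raw
#' lengths of the two tutorial levels (no normalization). Both are z-scored
#' over the scored population: positive values are above-average
#' performance.
#'
#' @param traj trajectory table (columns participant_id, level, t_ms, x, y).
#' @inheritParams normalize_lengths
#' @return data.frame with one row per participant appearing in `traj`:
#'   `participant_id`, `tp`, `wf`, `n_levels_used`, `excluded_reason` (NA
#'   scores for excluded participants). Attributes: `exclusions` (counts per
#'   reason), `wf_variance_explained`, `tp_variance_explained`.
#' @export
compute_tp_wf <- function(traj,
                          tutorial_levels = c(1L, 2L),
                          wayfinding_levels = c(6L, 7L, 8L, 11L)) {
  raw <- level_path_lengths(traj)
  norm <- normalize_lengths(raw, tutorial_levels, wayfinding_levels)
  lengths <- norm$lengths
  if (nrow(lengths) < 2) {
    stop("fewer than 2 scorable participants", call. = FALSE)
  }
  wf_mat <- as.matrix(lengths[paste0("norm_", wayfinding_levels)])
  tp_mat <- as.matrix(lengths[paste0("raw_", tutorial_levels)])
  wf_pc <- first_pc_scores(wf_mat)
  tp_pc <- first_pc_scores(tp_mat)
  scored <- data.frame(
    participant_id = lengths$participant_id,
    tp = compose_performance(tp_pc$scores),
    wf = compose_performance(wf_pc$scores),
    n_levels_used = length(tutorial_levels) + length(wayfinding_levels),
    excluded_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (nrow(norm$exclusions) > 0) {
    excl <- data.frame(
      participant_id = norm$exclusions$participant_id,
      tp = NA_real_, wf = NA_real_, n_levels_used = 0L,
      excluded_reason = norm$exclusions$reason,
      stringsAsFactors = FALSE
    )
    scored <- rbind(scored, excl)
  }
  scored <- scored[order(scored$participant_id), ]
  rownames(scored) <- NULL
  attr(scored, "exclusions") <- table(norm$exclusions$reason)
  attr(scored, "wf_variance_explained") <- wf_pc$variance_explained
  attr(scored, "tp_variance_explained") <- tp_pc$variance_explained
  scored
}

#' Write per-participant performance scores as CSV
#' @param scores output of [compute_tp_wf()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
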