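#' Default level geometry for the synthetic navigation task
#'
#' Two tutorial levels (ids 1 and 2; the target is visible from the start, so
#' no spatial ability is needed) and four wayfinding levels (ids 6, 7, 8 and
#' 11) defined by ordered checkpoint polylines in pixel coordinates.
#'
#' @return named list of level specs: `level` (integer id), `tutorial`
#'   (flag), `checkpoints` (matrix with columns x, y; the first row is the
#'   start position).
#' @export
default_level_specs <- function() {
  mk <- function(level, tutorial, xy) {
    list(level = as.integer(level), tutorial = tutorial,
         checkpoints = matrix(xy, ncol = 2, byrow = TRUE,
                              dimnames = list(NULL, c("x", "y"))))
  }
  list(
    `1`  = mk(1, TRUE,  c(100, 100, 300, 100)),
    `2`  = mk(2, TRUE,  c(100, 100, 220, 260)),
    `6`  = mk(6, FALSE, c(100, 100, 260, 180, 180, 320, 60, 220)),
    `7`  = mk(7, FALSE, c(80, 80, 300, 120, 340, 300, 160, 260)),
    `8`  = mk(8, FALSE, c(100, 300, 240, 80, 400, 240, 260, 380)),
    `11` = mk(11, FALSE, c(60, 60, 240, 100, 380, 240, 300, 400, 120, 340))
  )
}

#' Configuration of the synthetic trajectory generator
#'
#' @param level_specs list of level specs as produced by
#'   [default_level_specs()]; by default exactly 2 tutorial and 4 wayfinding
#'   levels.
#' @param sample_period_ms sampling period of the recorded coordinates,
#'   default 500 ms.
#' @param speed_px_s boat speed in pixels per second; together with
#'   `sample_period_ms` this sets the step length between samples.
#' @param detour_gain scales how strongly `(1 - navigation skill)` inflates
#'   wayfinding paths through perpendicular detour waypoints; 0 removes all
#'   skill signal from the trajectories.
#' @param motor_noise_sd pixel SD of per-sample hand jitter at motor skill 0
#'   (scaled by `1 - motor_skill`); affects all levels.
#' @param motor_scale_gain exponent gain of the per-participant common scale
#'   factor `exp(gain * (1 - motor_skill))` applied to all of a
#'   participant's coordinates (device handling: less skilled participants
#'   steer longer, more meandering paths everywhere). Tutorial normalization
#'   cancels it, so it carries motor skill into TP without contaminating WF.
#'   At motor skill 1 the factor is exactly 1.
#' @param seed RNG seed.
#' @return a `trajectory_config` list.
#' @export
trajectory_config <- function(level_specs = default_level_specs(),
                              sample_period_ms = 500,
                              speed_px_s = 50,
                              detour_gain = 1,
                              motor_noise_sd = 6,
                              motor_scale_gain = 1,
                              seed = NULL) {
  if (sample_period_ms <= 0) stop("sample_period_ms must be > 0", call. = FALSE)
  if (speed_px_s <= 0) stop("speed_px_s must be > 0", call. = FALSE)
  tut <- vapply(level_specs, function(s) isTRUE(s$tutorial), logical(1))
  if (length(level_specs) == 0 || sum(tut) < 1 || sum(!tut) < 1) {
    stop("level_specs needs at least one tutorial and one wayfinding level",
         call. = FALSE)
  }
  structure(list(level_specs = level_specs,
                 sample_period_ms = sample_period_ms,
                 speed_px_s = speed_px_s,
                 detour_gain = detour_gain,
                 motor_noise_sd = motor_noise_sd,
                 motor_scale_gain = motor_scale_gain,
                 seed = seed),
            class = "trajectory_config")
}

# Sample one polyline at (approximately) fixed step length, preserving all
# vertices so that a jitter-free path has exactly the polyline's length.
sample_polyline <- function(verts, step) {
  pts <- verts[1, , drop = FALSE]
  for (v in seq_len(nrow(verts) - 1L)) {
    a <- verts[v, ]; b <- verts[v + 1L, ]
    len <- sqrt(sum((b - a)^2))
    if (len <= 0) next
    n_in <- max(0L, floor(len / step - 1e-9))
    if (n_in > 0) {
      tt <- seq_len(n_in) * step / len
      pts <- rbind(pts, cbind(a[1] + tt * (b[1] - a[1]),
                              a[2] + tt * (b[2] - a[2])))
    }
    pts <- rbind(pts, b)
  }
  pts
}

#' Generate synthetic game trajectories for a cohort
#'
#' For every participant and level, builds a route through the level's
#' checkpoints and samples it every `sample_period_ms`. On wayfinding levels
#' a detour waypoint is inserted into each checkpoint gap, displaced
#' perpendicular to the gap by an amount proportional to
#' `detour_gain * (1 - navigation skill)`, so expected path length increases
#' monotonically as skill decreases. Per-sample Gaussian jitter scaled by
#' `1 - motor skill` models handling noise on all levels, and all
#' coordinates of a participant are multiplied by the common scale factor
#' `exp(motor_scale_gain * (1 - motor skill))`; tutorial paths therefore
#' depend only on motor skill.
#'
#' With `skill = 1` and `motor_noise_sd = 0` the sampled path lies exactly on
#' the checkpoint polyline and its length equals the sum of straight-line
#' checkpoint gaps.
#'
#' @param records cohort data.frame (only `participant_id` is used).
#' @param tconfig a [trajectory_config()].
#' @param truth ground truth from [generate_cohort()] (latent skills); must
#'   cover every participant in `records`.
#' @return a `data.frame` with columns `participant_id`, `level`, `t_ms`,
#'   `x`, `y`, sorted by (participant_id, level, t_ms).
#' @export
generate_trajectories <- function(records, tconfig, truth) {
  stopifnot(inherits(tconfig, "trajectory_config"))
  if (nrow(records) == 0) {
    return(data.frame(participant_id = character(0), level = integer(0),
                      t_ms = numeric(0), x = numeric(0), y = numeric(0)))
  }
  sk <- truth$participants
  idx <- match(records$participant_id, sk$participant_id)
  if (anyNA(idx)) {
    stop("ground truth is missing latent skills for some participants",
         call. = FALSE)
  }
  nav <- sk$nav_skill[idx]
  motor <- sk$motor_skill[idx]
  if (!is.null(tconfig$seed)) set.seed(tconfig$seed)
  n <- nrow(records)
  step <- tconfig$speed_px_s * tconfig$sample_period_ms / 1000
  dev_scale <- exp(tconfig$motor_scale_gain * (1 - motor))

  nlev <- length(tconfig$level_specs)
  xs <- vector("list", n * nlev)
  ys <- vector("list", n * nlev)
  counts <- integer(n * nlev)
  lev_ids <- integer(n * nlev)
  slot <- 0L
  for (p in seq_len(n)) {
    jitter_sd <- tconfig$motor_noise_sd * (1 - motor[p])
    for (spec in tconfig$level_specs) {
      cp <- spec$checkpoints
      verts <- cp
      if (!spec$tutorial && tconfig$detour_gain > 0) {
        # one perpendicular detour waypoint per checkpoint gap
        ngap <- nrow(cp) - 1L
        amp <- tconfig$detour_gain * (1 - nav[p]) * 0.5 *
          abs(stats::rnorm(ngap))
        side <- sign(stats::runif(ngap) - 0.5)
        verts <- matrix(0, nrow(cp) + ngap, 2)
        verts[1, ] <- cp[1, ]
        for (g in seq_len(ngap)) {
          a <- cp[g, ]; b <- cp[g + 1L, ]
          gap <- b - a
          len <- sqrt(sum(gap^2))
          perp <- c(-gap[2], gap[1]) / len
          mid <- (a + b) / 2 + side[g] * amp[g] * len * perp
          verts[2L * g, ] <- mid
          verts[2L * g + 1L, ] <- b
        }
      }
      pts <- sample_polyline(verts, step)
      m <- nrow(pts)
      if (jitter_sd > 0 && m > 1) {
        pts[-1, ] <- pts[-1, ] + matrix(stats::rnorm(2 * (m - 1), 0, jitter_sd),
                                        m - 1, 2)
      }
      slot <- slot + 1L
      xs[[slot]] <- pts[, 1] * dev_scale[p]
      ys[[slot]] <- pts[, 2] * dev_scale[p]
      counts[slot] <- m
      lev_ids[slot] <- spec$level
    }
  }
  res <- data.table::data.table(
    participant_id = rep(rep(records$participant_id, each = nlev), counts),
    level = rep(lev_ids, counts),
    t_ms = (sequence(counts) - 1) * tconfig$sample_period_ms,
    x = unlist(xs, use.names = FALSE),
    y = unlist(ys, use.names = FALSE)
  )
  data.table::setorder(res, participant_id, level, t_ms)
  data.table::setDF(res)
  res
}

#' Write / read trajectory samples as CSV
#'
#' Columns: participant_id, level, t_ms, x, y; rows sorted by
#' (participant_id, level, t_ms).
#'
#' @param traj trajectory data.frame.
#' @param path file path.
#' @return `path` (write) or the trajectory data.frame (read).
#' @export
write_trajectories_csv <- function(traj, path) {
  cols <- c("participant_id", "level", "t_ms", "x", "y")
  stopifnot(all(cols %in% names(traj)))
  data.table::fwrite(traj[, cols], path)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @export
read_trajectories_csv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE)
  need <- c("participant_id", "level", "t_ms", "x", "y")
  if (!all(need %in% names(d))) {
    stop("trajectory file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  d
}
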