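#' @title Behavioral metrics for reaching trajectories
#'
#' @description Trajectories are tabular: one row per time sample with columns
#' `t_s`, `x_m`, `y_m`, `vx_ms`, `vy_ms` (and optionally `fx_N`, `fy_N`),
#' SI units, origin at the start-circle center, target at (0, 0.150) m.
#' Metrics are reported in millimeters, signed with +x positive.
#' @name metrics
NULL

SPEED_STOP_MS <- 0.020    # endpoint speed threshold, m/s
LD_Y_M        <- 0.075    # mid-reach line for lateral deviation, m
TARGET_Y_M    <- 0.150
TARGET_RADIUS_MM <- 7.5

hand_speed <- function(traj) sqrt(traj$vx_ms^2 + traj$vy_ms^2)

# index of the movement endpoint: first sample at which speed falls back
# below the stop threshold after onset (onset = first sample at/above it).
endpoint_index <- function(traj) {
  sp <- hand_speed(traj)
  onset <- which(sp >= SPEED_STOP_MS)[1L]
  if (is.na(onset)) return(list(idx = nrow(traj), flagged = TRUE))
  rel <- which(sp[seq.int(onset, length(sp))] < SPEED_STOP_MS)[1L]
  if (is.na(rel)) list(idx = nrow(traj), flagged = TRUE)
  else list(idx = onset + rel - 1L, flagged = FALSE)
}

#' Target error (TE)
#'
#' Signed x-deviation, in mm, of the final hand position from the straight
#' start-to-target line. The final position is taken at the first sample
#' where hand speed falls below 20 mm/s after movement onset (the same rule
#' that triggers the endpoint lock); if the hand never slows below threshold
#' the last sample is used and the result carries `attr(, "flagged") = TRUE`.
#'
#' @param traj Trajectory table (see [metrics]).
#' @return TE in mm (signed, +x positive).
#' @export
target_error <- function(traj) {
  ep <- endpoint_index(traj)
  te <- traj$x_m[ep$idx] * 1000
  if (ep$flagged) attr(te, "flagged") <- TRUE
  te
}

# first crossing of a horizontal line y = y0 (m), linearly interpolated;
# NA if the trajectory never reaches y0.
first_y_crossing_x <- function(traj, y0) {
  y <- traj$y_m; x <- traj$x_m
  if (y[1L] >= y0) return(x[1L])
  i <- which(y[-1L] >= y0 & y[-length(y)] < y0)[1L]
  if (is.na(i)) return(NA_real_)
  w <- (y0 - y[i]) / (y[i + 1L] - y[i])
  x[i] + w * (x[i + 1L] - x[i])
}

#' Lateral deviation (LD)
#'
#' Signed x-deviation, in mm, of the hand path from the straight
#' start-to-target line at mid-reach (y = 75 mm), linearly interpolated at
#' the first crossing of that line. Undefined (NA) when the reach distance
#' is under 75 mm; such trials are excluded from analysis.
#'
#' @inheritParams target_error
#' @return LD in mm, or `NA` for an invalid (short) reach.
#' @export
lateral_deviation <- function(traj) {
  1000 * first_y_crossing_x(traj, LD_Y_M)
}

#' Reach distance
#'
#' Farthest forward (y) extent of the hand path, mm. Trials with reach
#' distance below 75 mm are invalid: the lateral deviation cannot be read.
#'
#' @inheritParams target_error
#' @export
reach_distance <- function(traj) 1000 * max(traj$y_m)

#' Resample the hand path laterally on a y grid
#'
#' Interpolates x (mm) at fixed forward positions, used to average
#' trajectories across participants. The default grid is the 16 reporting
#' positions from 7.5 mm (the target radius) to 150 mm (the target).
#'
#' @inheritParams target_error
#' @param y_grid_mm Forward positions, mm.
#' @return Named numeric vector of x, mm; `NA` past the reach extent.
#' @export
resample_x_at_y <- function(traj,
                            y_grid_mm = c(7.5, 10, 20, 30, 40, 50, 60, 70,
                                          80, 90, 100, 110, 120, 130, 140, 150)) {
  out <- vapply(y_grid_mm / 1000, function(y0) first_y_crossing_x(traj, y0),
                numeric(1L))
  1000 * stats::setNames(out, paste0("y", y_grid_mm))
}

#' Per-trial metric record
#'
#' @inheritParams target_error
#' @return List with `TE_mm`, `LD_mm`, `reach_mm`, `valid` (reach >= 75 mm)
#'   and `flagged` (no sub-threshold endpoint sample).
#' @export
trial_metrics <- function(traj) {
  te <- target_error(traj)
  rd <- reach_distance(traj)
  list(TE_mm = as.numeric(te),
       LD_mm = lateral_deviation(traj),
       reach_mm = rd,
       valid = rd >= 75,
       flagged = isTRUE(attr(te, "flagged")))
}

#' Canonical trial epochs
#'
#' The six reporting epochs: 1st, 3rd-5th and last-20 (136th-155th) adaptation
#' trials, and 1st, 3rd-5th and last-20 (131st-150th) de-adaptation trials.
#' Trial indices are within-phase.
#'
#' @return Named list with elements `phase` and `trials` per epoch.
#' @export
epoch_spec <- function() {
  list(
    adapt_1      = list(phase = "adaptation",    trials = 1L),
    adapt_3_5    = list(phase = "adaptation",    trials = 3:5),
    adapt_last20 = list(phase = "adaptation",    trials = 136:155),
    deadapt_1      = list(phase = "de_adaptation", trials = 1L),
    deadapt_3_5    = list(phase = "de_adaptation", trials = 3:5),
    deadapt_last20 = list(phase = "de_adaptation", trials = 131:150)
  )
}

#' Epoch means of a per-trial series
#'
#' @param series Numeric per-trial values for one phase (indexed from trial 1).
#' @param windows Named list of integer trial windows; defaults to the three
#'   within-phase windows `{1}`, `{3..5}`, `{last 20}` are supplied by the
#'   caller via [epoch_spec()].
#' @param na.rm Drop excluded (NA) trials within a window.
#' @return Named numeric vector of window means.
#' @export
epoch_summary <- function(series, windows, na.rm = TRUE) {
  stopifnot(is.list(windows), !is.null(names(windows)))
  vapply(windows, function(w) {
    stopifnot(all(w >= 1L), all(w <= length(series)))
    mean(series[w], na.rm = na.rm)
  }, numeric(1L))
}

#' Baseline subtraction
#'
#' Subtracts a participant's baseline LD (mean over the last 20 baseline
#' trials) from an LD series, so reported deviations are relative to that
#' participant's own null trajectory.
#'
#' @param series Numeric LD series, mm.
#' @param baseline Scalar baseline mean, mm (e.g.
#'   `mean(tail(baseline_ld, 20))`).
#' @export
baseline_subtract <- function(series, baseline) {
  stopifnot(length(baseline) == 1L)
  series - baseline
}

#' Baseline screening of a participant
#'
#' Participants proceed only if the magnitude of their LD averaged over the
#' last 20 baseline trials is strictly less than 4.5 mm, ensuring comparable
#' straight null trajectories across groups.
#'
#' @param baseline_ld_mm Per-trial baseline LD series, mm.
#' @param threshold_mm Screening bound, mm.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
screen_participant <- function(baseline_ld_mm, threshold_mm = 4.5) {
  m <- mean(utils::tail(baseline_ld_mm, 20L), na.rm = TRUE)
  abs(m) < threshold_mm
}

#' Flag an unstable participant
#'
#' A participant is excluded when, over the last 100 de-adaptation trials,
#' the LD makes at least three large jumps across the x-axis (consecutive
#' trials with opposite LD sign and |change| > 20 mm) AND the participant's
#' last-20-trial LD mean is an outlier (beyond 3 s.d.) relative to the group
#' of last-20 means.
#'
#' @param deadapt_ld_mm The participant's full de-adaptation LD series, mm.
#' @param group_last20_means_mm Last-20-trial LD means of all participants in
#'   the group (including this one), mm.
#' @param jump_mm Jump magnitude threshold, mm.
#' @param n_jumps Minimum number of jumps.
#' @return `TRUE` if the participant should be excluded.
#' @export
flag_unstable_participant <- function(deadapt_ld_mm, group_last20_means_mm,
                                      jump_mm = 20, n_jumps = 3L) {
  last100 <- utils::tail(deadapt_ld_mm, 100L)
  d <- diff(last100)
  crossing <- sign(last100[-length(last100)]) * sign(last100[-1L]) < 0
  jumps <- sum(crossing & abs(d) > jump_mm, na.rm = TRUE)
  m <- mean(utils::tail(deadapt_ld_mm, 20L), na.rm = TRUE)
  mu <- mean(group_last20_means_mm, na.rm = TRUE)
  sdv <- stats::sd(group_last20_means_mm, na.rm = TRUE)
  jumps >= n_jumps && is.finite(sdv) && sdv > 0 && abs(m - mu) > 3 * sdv
}

#' Trial exclusion
#'
#' Removes trials whose reach distance is under 75 mm (LD undefined there).
#'
#' @param records Data frame with at least a `reach_mm` column (e.g. rows of
#'   [trial_metrics()] results).
#' @return The data frame restricted to valid trials.
#' @export
exclude_short_reaches <- function(records) {
  records[records$reach_mm >= 75, , drop = FALSE]
}
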