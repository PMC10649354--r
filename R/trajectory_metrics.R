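# Step distances, daily distance traveled, and rate of travel.

#' Collapse stationary runs of fixes
#'
#' Consecutive fixes at an identical planar position are collapsed to the
#' first, so the elapsed time to the next distinct position is preserved in
#' the following step. Rate of travel is defined over position changes
#' (distance over the time taken to change location), so speed is computed on
#' this collapsed series.
#'
#' @param traj planar `gps_trajectory`.
#' @return `gps_trajectory` with stationary runs collapsed.
#' @export
collapse_stationary <- function(traj) {
  stopifnot(inherits(traj, "gps_trajectory"))
  if (traj$crs != "planar") stop("collapse_stationary needs a planar trajectory")
  f <- traj$fixes
  n <- nrow(f)
  if (n <= 1L) return(traj)
  same <- c(FALSE, f$x[-1L] == f$x[-n] & f$y[-1L] == f$y[-n])
  keep <- !same
  out <- f[keep, , drop = FALSE]
  # a long stationary run is not a recording gap: remember the largest raw
  # inter-fix spacing absorbed into the step leading to each kept fix, so
  # step validity is judged on actual recording continuity
  if (n > 1L) {
    raw_dt <- as.numeric(diff(f$time), units = "secs")
    grp <- cumsum(keep)[-1L]          # collapsed step each raw step feeds into
    out$max_raw_gap_s <- c(NA_real_,
                           as.numeric(tapply(raw_dt, grp, max)))[seq_len(nrow(out))]
  }
  traj$fixes <- out
  rownames(traj$fixes) <- NULL
  traj
}

#' Per-step distance and speed series
#'
#' Euclidean (Pythagorean) distance between sequential positions and speed in
#' m/min over each step. Steps whose elapsed time exceeds `max_gap_s` (data
#' gaps, collar changes) are marked invalid and excluded from daily sums.
#'
#' @param traj planar `gps_trajectory`, usually stationary-collapsed first.
#' @param max_gap_s longest step duration still treated as continuous
#'   recording (default 300 s).
#' @return data.frame of class `step_series`: `t_start`, `t_end`, `dt_s`,
#'   `distance_m`, `speed_m_per_min`, `valid`.
#' @export
step_metrics <- function(traj, max_gap_s = 300) {
  stopifnot(inherits(traj, "gps_trajectory"))
  if (traj$crs != "planar") stop("step_metrics needs a planar trajectory")
  f <- traj$fixes
  if (nrow(f) < 2L)
    return(structure(data.frame(t_start = f$time[0], t_end = f$time[0],
                                dt_s = numeric(0), distance_m = numeric(0),
                                speed_m_per_min = numeric(0), valid = logical(0)),
                     class = c("step_series", "data.frame")))
  dt <- as.numeric(diff(f$time), units = "secs")
  if (any(dt <= 0)) stop("non-monotone timestamps; clean the trajectory first")
  d <- sqrt(diff(f$x)^2 + diff(f$y)^2)
  # recording continuity: on a stationary-collapsed series, judge gaps by the
  # raw fix spacing absorbed into each step, not the collapsed duration
  gap <- if ("max_raw_gap_s" %in% names(f)) f$max_raw_gap_s[-1L] else dt
  gap[is.na(gap)] <- dt[is.na(gap)]
  out <- data.frame(t_start = f$time[-nrow(f)], t_end = f$time[-1L], dt_s = dt,
                    distance_m = d, speed_m_per_min = d / (dt / 60),
                    valid = gap <= max_gap_s)
  class(out) <- c("step_series", "data.frame")
  out
}

#' Daily distance traveled
#'
#' Sum of valid step distances, the m/day metric. Summing over any partition
#' of a day's steps gives the same total.
#'
#' @param steps `step_series` for one daily segment.
#' @return distance in meters.
#' @export
daily_distance <- function(steps) {
  stopifnot(inherits(steps, "step_series"))
  sum(steps$distance_m[steps$valid])
}

#' Mean rate of travel
#'
#' Distance over elapsed time, m/min. With `moving_only = TRUE` (default) the
#' denominator is the time spent changing position — compute it on a
#' stationary-collapsed series so resting runs are excluded, which is why
#' mean rates exceed `daily distance / 1440`. With `moving_only = FALSE` the
#' denominator is all valid step time (wall-clock style).
#'
#' @param steps `step_series`.
#' @param moving_only drop zero-distance steps from the denominator.
#' @return m/min.
#' @export
mean_travel_rate <- function(steps, moving_only = TRUE) {
  stopifnot(inherits(steps, "step_series"))
  s <- steps[steps$valid, , drop = FALSE]
  if (moving_only) s <- s[s$distance_m > 0, , drop = FALSE]
  if (!nrow(s)) return(0)
  sum(s$distance_m) / (sum(s$dt_s) / 60)
}

#' Thin a trajectory to a coarser sampling interval
#'
#' Keeps the fix nearest each interval tick, emulating loggers programmed at
#' longer fix intervals; used to quantify interpolation error against the
#' native 1 Hz record.
#'
#' @param traj `gps_trajectory`.
#' @param interval_s target interval, at least the native spacing.
#' @return thinned `gps_trajectory`.
#' @export
resample_trajectory <- function(traj, interval_s) {
  stopifnot(inherits(traj, "gps_trajectory"), interval_s > 0)
  tt <- as.numeric(traj$fixes$time)
  native <- stats::median(diff(tt))
  if (interval_s < native)
    stop("interval_s is smaller than the native fix spacing")
  ticks <- seq(tt[1L], tt[length(tt)], by = interval_s)
  # nearest fix per tick: fixes are time-sorted, so compare the two bracketing fixes
  lo <- findInterval(ticks, tt, all.inside = TRUE)
  hi <- pmin(lo + 1L, length(tt))
  idx <- unique(c(ifelse(abs(tt[lo] - ticks) <= abs(tt[hi] - ticks), lo, hi),
                  length(tt)))  # keep the track endpoint
  out <- traj
  out$fixes <- traj$fixes[idx, , drop = FALSE]
  rownames(out$fixes) <- NULL
  out
}

#' Daily movement metrics for one daily segment
#'
#' Convenience wrapper: collapse stationary runs, compute steps, and return a
#' one-row summary (distance, both rate-of-travel estimators, fix count, and
#' the coverage/excluded flags set by [split_days()]).
#'
#' @param day_traj one daily `gps_trajectory` segment.
#' @param max_gap_s passed to [step_metrics()].
#' @return one-row data.frame.
#' @export
daily_metrics <- function(day_traj, max_gap_s = 300) {
  stopifnot(inherits(day_traj, "gps_trajectory"))
  collapsed <- collapse_stationary(day_traj)
  excluded <- isTRUE(attr(day_traj, "excluded"))
  date <- attr(day_traj, "date")
  if (is.null(date)) date <- as.Date(format(day_traj$fixes$time[1L], "%Y-%m-%d"))
  if (nrow(collapsed$fixes) < 2L) {
    return(data.frame(animal_id = day_traj$animal_id, paddock_id = day_traj$paddock_id,
                      date = date, distance_m_per_day = 0,
                      rate_moving_m_per_min = 0, rate_elapsed_m_per_min = 0,
                      n_fixes = nrow(day_traj$fixes),
                      coverage = attr(day_traj, "coverage") %||% NA_real_,
                      excluded = excluded, stringsAsFactors = FALSE))
  }
  steps <- step_metrics(collapsed, max_gap_s = max_gap_s)
  data.frame(animal_id = day_traj$animal_id, paddock_id = day_traj$paddock_id,
             date = date, distance_m_per_day = daily_distance(steps),
             rate_moving_m_per_min = mean_travel_rate(steps, moving_only = TRUE),
             rate_elapsed_m_per_min = mean_travel_rate(steps, moving_only = FALSE),
             n_fixes = nrow(day_traj$fixes),
             coverage = attr(day_traj, "coverage") %||% NA_real_,
             excluded = excluded, stringsAsFactors = FALSE)
}
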