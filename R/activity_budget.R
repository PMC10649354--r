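# Speed-threshold behavioral classification and daily activity budgets.

#' Speed thresholds for behavioral classification
#'
#' Movement slower than `rest_max_m_per_min` is resting (all stationary
#' activity, including rumination), speeds between the two thresholds
#' (inclusive) are grazing, and faster movement is traveling. Defaults are
#' the cattle calibration in wide use for grazing steers: 2.34 and 25 m/min.
#'
#' @param rest_max_m_per_min upper bound (exclusive) of the resting band.
#' @param travel_min_m_per_min lower bound (exclusive) of the traveling band.
#' @return object of class `speed_thresholds`.
#' @export
speed_thresholds <- function(rest_max_m_per_min = 2.34, travel_min_m_per_min = 25) {
  if (!(rest_max_m_per_min > 0 && travel_min_m_per_min > rest_max_m_per_min))
    stop("need 0 < rest_max < travel_min")
  structure(list(rest_max = rest_max_m_per_min, travel_min = travel_min_m_per_min),
            class = "speed_thresholds")
}

#' Classify movement speed into an activity
#'
#' Band edges go to grazing: the grazing band is read as inclusive
#' ("between 2.34 and 25 m/min") while resting and traveling are strict
#' ("lower than" / "greater than").
#'
#' @param v_m_per_min speed in m/min, vectorized, non-negative.
#' @param thresholds `speed_thresholds`.
#' @return factor with levels resting, grazing, traveling.
#' @export
classify_speed <- function(v_m_per_min, thresholds = speed_thresholds()) {
  stopifnot(inherits(thresholds, "speed_thresholds"))
  if (any(v_m_per_min < 0, na.rm = TRUE)) stop("negative speed")
  cls <- ifelse(v_m_per_min < thresholds$rest_max, "resting",
                ifelse(v_m_per_min <= thresholds$travel_min, "grazing", "traveling"))
  factor(cls, levels = c("resting", "grazing", "traveling"))
}

#' Daily activity budget from a step series
#'
#' Time in each activity is the sum of step durations in that speed class;
#' stationary collapsed runs carry their full elapsed time at near-zero speed
#' and therefore count as resting. Percentages are of total classified time
#' (valid steps), not wall-clock 24 h, so dropout days do not distort the
#' budget.
#'
#' @param steps `step_series` for one daily segment (stationary-collapsed).
#' @param thresholds `speed_thresholds`.
#' @return one-row data.frame: `resting_pct`, `grazing_pct`, `traveling_pct`
#'   (summing to 100) and `classified_s`.
#' @export
daily_budget <- function(steps, thresholds = speed_thresholds()) {
  stopifnot(inherits(steps, "step_series"))
  s <- steps[steps$valid, , drop = FALSE]
  total <- sum(s$dt_s)
  if (!nrow(s) || total <= 0) stop("no classified time in this day")
  cls <- classify_speed(s$speed_m_per_min, thresholds)
  secs <- vapply(levels(cls), function(l) sum(s$dt_s[cls == l]), 0)
  pct <- 100 * secs / total
  data.frame(resting_pct = pct[["resting"]], grazing_pct = pct[["grazing"]],
             traveling_pct = pct[["traveling"]], classified_s = total)
}

#' Daily activity budget for a daily trajectory segment
#'
#' Collapses stationary runs, computes steps, and tallies the dt-weighted
#' budget; labels are attached from the segment metadata.
#'
#' @param day_traj daily `gps_trajectory`.
#' @param thresholds `speed_thresholds`.
#' @param max_gap_s passed to [step_metrics()].
#' @return one-row data.frame with ids, date, and the three percentages.
#' @export
activity_budget <- function(day_traj, thresholds = speed_thresholds(),
                            max_gap_s = 300) {
  collapsed <- collapse_stationary(day_traj)
  steps <- step_metrics(collapsed, max_gap_s = max_gap_s)
  b <- daily_budget(steps, thresholds)
  date <- attr(day_traj, "date")
  if (is.null(date)) date <- as.Date(format(day_traj$fixes$time[1L], "%Y-%m-%d"))
  cbind(data.frame(animal_id = day_traj$animal_id,
                   paddock_id = day_traj$paddock_id, date = date,
                   stringsAsFactors = FALSE), b)
}
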