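#' Daily period scheme
#'
#' The day is partitioned into three half-open windows by local clock hour:
#' \[00:00, 11:00), \[11:00, 16:00), \[16:00, 24:00). A stay belongs to the
#' period containing its start time.
#'
#' @param boundaries Interior hour boundaries (increasing, within (0, 24)).
#' @return Object of class `period_scheme`.
#' @export
period_scheme <- function(boundaries = c(11, 16)) {
  stopifnot(all(diff(c(0, boundaries, 24)) > 0))
  structure(list(boundaries = boundaries), class = "period_scheme")
}

stay_period <- function(stays, scheme, tz_offset_hours) {
  findInterval(local_hour(stays$start, tz_offset_hours), scheme$boundaries)
}

#' Observed (date, period) pairs
#'
#' A (local date, period) block counts as observed iff at least one of the
#' user's stays starts within it.
#'
#' @param stays One user's stays (`start` column).
#' @param scheme A [period_scheme()].
#' @param tz_offset_hours Fixed local-time offset from UTC, hours.
#' @return Data.frame with columns `date` and `period` (0-based), unique rows.
#' @export
observed_periods <- function(stays, scheme = period_scheme(),
                             tz_offset_hours = -8) {
  if (nrow(stays) == 0L)
    return(data.frame(date = as.Date(character(0)), period = integer(0)))
  unique(data.frame(date = local_date(stays$start, tz_offset_hours),
                    period = stay_period(stays, scheme, tz_offset_hours)))
}

#' Temporal frequency of fast food visits (FF visits/time)
#'
#' Percentage of a user's observed daily periods that contain at least one
#' stay attributed to a fast food outlet.
#'
#' @param stays One user's attributed stays (needs `start`, `is_ff`).
#' @inheritParams observed_periods
#' @return Percentage in \[0, 100\], or `NA` when the user has no observed
#'   periods (such users are excluded from aggregation).
#' @export
ff_visits_time <- function(stays, scheme = period_scheme(),
                           tz_offset_hours = -8) {
  obs <- observed_periods(stays, scheme, tz_offset_hours)
  if (nrow(obs) == 0L) return(NA_real_)
  ff <- stays[stays$is_ff, , drop = FALSE]
  ff_periods <- unique(data.frame(date = local_date(ff$start, tz_offset_hours),
                                  period = stay_period(ff, scheme,
                                                       tz_offset_hours)))
  100 * nrow(ff_periods) / nrow(obs)
}

#' Relative frequency of fast food to all food visits (FF visits/food)
#'
#' Percentage of a user's food-outlet visits (each attributed stay counts
#' once) that were to fast food outlets.
#'
#' @param stays One user's attributed stays (needs `is_food`, `is_ff`).
#' @return Percentage, or `NA` when the user has no food visits (flagged).
#' @export
ff_visits_food <- function(stays) {
  n_food <- sum(stays$is_food)
  if (n_food == 0L) return(NA_real_)
  100 * sum(stays$is_ff) / n_food
}

#' Average trips per observation day
#'
#' Trips (trajectories between consecutive stays) divided by the number of
#' observation days.
#'
#' @param stays One user's stays, chronologically ordered.
#' @inheritParams observed_periods
#' @return Rate, or `NA` when the user has no observation days.
#' @export
trips_per_day <- function(stays, tz_offset_hours = -8) {
  days <- observation_days(stays, tz_offset_hours)
  if (length(days) == 0L) return(NA_real_)
  count_trips(stays) / length(days)
}

# per-stay overlap (seconds) with the nightly window [night_start, night_end)
# hours local time, wrapping midnight
night_overlap_s <- function(start, end, tz_offset_hours,
                            night_start = 22, night_end = 6) {
  s <- as.numeric(local_shift(start, tz_offset_hours))
  e <- as.numeric(local_shift(end, tz_offset_hours))
  d0 <- floor(s / 86400)
  span <- max(0, floor(e / 86400) - d0)
  total <- numeric(length(s))
  for (off in (-1):max(span)) {
    win_s <- (d0 + off) * 86400 + night_start * 3600
    win_e <- (d0 + off + 1) * 86400 + night_end * 3600
    total <- total + pmax(0, pmin(e, win_e) - pmax(s, win_s))
  }
  total
}

#' Infer a user's home neighborhood
#'
#' The home neighborhood is the one containing the majority of the user's
#' nighttime activity (total stay duration overlapping the 22:00–06:00 local
#' window), with stay centroids assigned to neighborhoods by point-in-polygon.
#' Ties resolve to the neighborhood with more of the user's stays, then the
#' smaller id. Users with no nighttime activity get `NA` (flagged and excluded
#' from aggregation).
#'
#' @param stays One user's stays.
#' @param neighborhoods Neighborhood `polygon_set`.
#' @param night Night window as `c(start_hour, end_hour)`, wrapping midnight.
#' @inheritParams observed_periods
#' @return Neighborhood id or `NA_character_`.
#' @export
infer_home <- function(stays, neighborhoods, night = c(22, 6),
                       tz_offset_hours = -8) {
  if (nrow(stays) == 0L) return(NA_character_)
  nb <- locate_points(stays$centroid_lon, stays$centroid_lat, neighborhoods)
  dur <- night_overlap_s(stays$start, stays$end, tz_offset_hours,
                         night[1], night[2])
  ok <- !is.na(nb)
  if (!any(ok) || sum(dur[ok]) == 0) return(NA_character_)
  tally <- data.frame(nb = nb[ok], dur = dur[ok])
  agg <- stats::aggregate(dur ~ nb, tally, sum)
  cnt <- table(factor(tally$nb, levels = agg$nb))
  agg$n <- as.integer(cnt[agg$nb])
  if (max(agg$dur) == 0) return(NA_character_)
  agg <- agg[order(-agg$dur, -agg$n, agg$nb), , drop = FALSE]
  agg$nb[1]
}

#' Per-user mobility metrics
#'
#' Computes, for every user in an attributed stay table, the home
#' neighborhood, FF visits/time, FF visits/food, trips/day, and bookkeeping
#' counts.
#'
#' @param stays Attributed stays with a `user_id` column.
#' @param neighborhoods Neighborhood `polygon_set`.
#' @param scheme A [period_scheme()].
#' @param night Night window hours.
#' @inheritParams observed_periods
#' @return Data.frame: `user_id`, `home_neighborhood_id`,
#'   `ff_visits_time_pct`, `ff_visits_food_pct`, `trips_per_day`,
#'   `n_observed_periods`, `n_food_visits`, `n_ff_visits`,
#'   `n_observation_days`.
#' @export
compute_user_metrics <- function(stays, neighborhoods,
                                 scheme = period_scheme(), night = c(22, 6),
                                 tz_offset_hours = -8) {
  dt <- data.table::as.data.table(stays)
  data.table::setorder(dt, user_id, start)
  out <- dt[, {
    sd <- as.data.frame(.SD)
    list(home_neighborhood_id = infer_home(sd, neighborhoods, night,
                                           tz_offset_hours),
         ff_visits_time_pct = ff_visits_time(sd, scheme, tz_offset_hours),
         ff_visits_food_pct = ff_visits_food(sd),
         trips_per_day = trips_per_day(sd, tz_offset_hours),
         n_observed_periods = nrow(observed_periods(sd, scheme,
                                                    tz_offset_hours)),
         n_food_visits = sum(sd$is_food),
         n_ff_visits = sum(sd$is_ff),
         n_observation_days = length(observation_days(sd, tz_offset_hours)))
  }, by = user_id]
  as.data.frame(out)
}
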