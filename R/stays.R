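#' Stay detection parameters
#'
#' Defaults follow the standard configuration for smartphone ping streams: a
#' 50 m roaming distance, a 5 minute minimum dwell, and at least two pings per
#' stay.
#'
#' @param d_roam_m Roaming distance in meters; a cluster is grown only while
#'   every member ping is strictly within this distance of the cluster's
#'   coordinate-wise median centroid.
#' @param min_duration_min Minimum stay duration in minutes (last ping minus
#'   first ping).
#' @param min_events Minimum number of pings in a stay.
#' @return An object of class `stay_params`.
#' @export
stay_params <- function(d_roam_m = 50, min_duration_min = 5, min_events = 2) {
  stopifnot(d_roam_m > 0, min_duration_min > 0, min_events > 0)
  structure(list(d_roam_m = d_roam_m, min_duration_min = min_duration_min,
                 min_events = as.integer(min_events)),
            class = "stay_params")
}

#' Detect stays in one user's ping stream
#'
#' Clusters a single user's time-sorted pings into dwell events ("stays") by
#' greedy sequential clustering: the next ping joins the current cluster iff,
#' after inclusion, the maximum haversine distance from any member ping to the
#' cluster's coordinate-wise median centroid stays strictly below `d_roam_m`.
#' On violation the cluster is closed — emitted as a stay when it contains at
#' least `min_events` pings and spans at least `min_duration_min` minutes —
#' and the violating ping opens the next cluster. The first and last member
#' pings mark the start and end of the stay.
#'
#' @param pings A data.frame with columns `timestamp` (POSIXct), `lat`, `lon`,
#'   sorted by timestamp; at most one user.
#' @param params A [stay_params()] object.
#' @return A data.frame of stays: `start`, `end` (POSIXct), `centroid_lat`,
#'   `centroid_lon`, `n_pings`, in chronological order.
#' @export
detect_stays <- function(pings, params = stay_params()) {
  stopifnot(inherits(params, "stay_params"))
  if (nrow(pings) == 0L) return(empty_stays())
  ts <- as.numeric(pings$timestamp)
  if (is.unsorted(ts)) stop("pings must be sorted by timestamp")
  if (!all(is.finite(pings$lat)) || !all(is.finite(pings$lon)))
    stop("non-finite coordinates")
  res <- detect_stays_cpp(ts, pings$lat, pings$lon, params$d_roam_m,
                          params$min_duration_min, params$min_events)
  data.frame(start = .POSIXct(res$start, tz = "UTC"),
             end = .POSIXct(res$end, tz = "UTC"),
             centroid_lat = res$centroid_lat,
             centroid_lon = res$centroid_lon,
             n_pings = res$n_pings)
}

empty_stays <- function() {
  data.frame(start = .POSIXct(numeric(0), tz = "UTC"),
             end = .POSIXct(numeric(0), tz = "UTC"),
             centroid_lat = numeric(0), centroid_lon = numeric(0),
             n_pings = integer(0))
}

#' Detect stays for every user in a ping table
#'
#' Applies [detect_stays()] per user (pings are sorted by timestamp within
#' user first) and stacks the results with a `user_id` column. The result is
#' independent of the interleaving order of users in the input.
#'
#' @param pings Data.frame with `user_id`, `timestamp`, `lat`, `lon`.
#' @inheritParams detect_stays
#' @return Data.frame of stays with a leading `user_id` column.
#' @export
detect_stays_by_user <- function(pings, params = stay_params()) {
  dt <- data.table::as.data.table(pings)
  if (nrow(dt) == 0L) return(cbind(user_id = character(0), empty_stays()))
  data.table::setorder(dt, user_id, timestamp)
  out <- dt[, detect_stays(.SD, params), by = user_id]
  as.data.frame(out)
}

#' Count trips in a stay sequence
#'
#' A trip is a trajectory between two consecutive stays, so a user with
#' `n` stays has `max(0, n - 1)` trips.
#'
#' @param stays Data.frame of one user's stays, chronologically ordered.
#' @return Integer trip count.
#' @export
count_trips <- function(stays) {
  max(0L, nrow(stays) - 1L)
}

#' Observation days
#'
#' The set of distinct local calendar dates on which a user has at least one
#' detected stay. Local dates are derived from a fixed UTC offset.
#'
#' @param stays Data.frame with a `start` column (POSIXct).
#' @param tz_offset_hours Fixed local-time offset from UTC, in hours.
#' @return Vector of `Date`s (possibly empty).
#' @export
observation_days <- function(stays, tz_offset_hours = -8) {
  if (nrow(stays) == 0L) return(as.Date(character(0)))
  sort(unique(local_date(stays$start, tz_offset_hours)))
}
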