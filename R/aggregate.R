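#' Aggregate user metrics into neighborhood contextual variables
#'
#' Arithmetic means and population variances of the per-user mobility metrics
#' over users whose inferred home lies in each neighborhood. Users without a
#' home neighborhood are dropped; per-metric means ignore users for whom the
#' metric is undefined. Neighborhoods with fewer than `min_users` resident
#' users are dropped with a warning (an aggregate-only reporting floor).
#'
#' @param user_metrics Output of [compute_user_metrics()].
#' @param min_users Minimum resident users per retained neighborhood.
#' @return Data.frame: `neighborhood_id`, `n_users`, `mean_ff_time_pct`,
#'   `mean_ff_food_pct`, `mean_trips_day`, `var_ff_time`, `var_ff_food`.
#' @export
aggregate_by_neighborhood <- function(user_metrics, min_users = 5) {
  um <- user_metrics[!is.na(user_metrics$home_neighborhood_id), , drop = FALSE]
  if (nrow(um) == 0L) {
    return(data.frame(neighborhood_id = character(0), n_users = integer(0),
                      mean_ff_time_pct = numeric(0),
                      mean_ff_food_pct = numeric(0),
                      mean_trips_day = numeric(0), var_ff_time = numeric(0),
                      var_ff_food = numeric(0)))
  }
  pop_var <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    mean((x - mean(x))^2)
  }
  dt <- data.table::as.data.table(um)
  out <- dt[, list(
    n_users = .N,
    mean_ff_time_pct = mean(ff_visits_time_pct, na.rm = TRUE),
    mean_ff_food_pct = mean(ff_visits_food_pct, na.rm = TRUE),
    mean_trips_day = mean(trips_per_day, na.rm = TRUE),
    var_ff_time = pop_var(ff_visits_time_pct),
    var_ff_food = pop_var(ff_visits_food_pct)),
    by = list(neighborhood_id = home_neighborhood_id)]
  drop <- out$n_users < min_users
  if (any(drop))
    warning(sum(drop), " neighborhood(s) dropped with fewer than ",
            min_users, " users")
  out <- out[!drop]
  data.table::setorder(out, neighborhood_id)
  as.data.frame(out)
}

#' Rescale neighborhood metrics to the 0-10 contextual scale
#'
#' Percentage-valued means are divided by 10 so that one scaled unit equals a
#' 10-percentage-point increase. Trips/day is already on a 0-10-compatible
#' scale and is left unscaled by default (`trips_mode = "identity"`);
#' `trips_mode = "minmax"` instead min-max rescales it onto \[0, 10\].
#'
#' @param nm Output of [aggregate_by_neighborhood()].
#' @param trips_mode `"identity"` or `"minmax"`.
#' @return `nm` with added `scaled_ff_time`, `scaled_ff_food`,
#'   `scaled_trips_day`.
#' @export
rescale_metrics <- function(nm, trips_mode = c("identity", "minmax")) {
  trips_mode <- match.arg(trips_mode)
  nm$scaled_ff_time <- nm$mean_ff_time_pct / 10
  nm$scaled_ff_food <- nm$mean_ff_food_pct / 10
  nm$scaled_trips_day <- if (trips_mode == "identity") {
    nm$mean_trips_day
  } else {
    rng <- range(nm$mean_trips_day, na.rm = TRUE)
    if (diff(rng) == 0) rep(0, nrow(nm)) else
      10 * (nm$mean_trips_day - rng[1]) / diff(rng)
  }
  nm
}

#' Link neighborhood contextual variables to survey respondents
#'
#' Attaches each respondent's residential neighborhood's scaled contextual
#' variables. Respondents whose neighborhood is missing or absent from the
#' metrics table (e.g., dropped below the user floor) are flagged in the
#' `linked` column and reported.
#'
#' @param respondents Respondent table with `neighborhood_id`.
#' @param nm Rescaled neighborhood metrics ([rescale_metrics()]).
#' @return `respondents` with `scaled_ff_time`, `scaled_ff_food`,
#'   `scaled_trips_day`, and logical `linked`.
#' @export
link_to_respondents <- function(respondents, nm) {
  idx <- match(respondents$neighborhood_id, nm$neighborhood_id)
  respondents$scaled_ff_time <- nm$scaled_ff_time[idx]
  respondents$scaled_ff_food <- nm$scaled_ff_food[idx]
  respondents$scaled_trips_day <- nm$scaled_trips_day[idx]
  respondents$linked <- !is.na(idx)
  nb <- respondents$neighborhood_id
  n_un <- sum(!respondents$linked & !is.na(nb) & nzchar(as.character(nb)))
  if (n_un > 0)
    message(n_un, " respondent(s) in neighborhoods without contextual metrics")
  respondents
}
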