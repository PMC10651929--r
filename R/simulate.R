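#' Simulate the smartphone mobility panel
#'
#' Generates each user's ping stream from a daily routine: an overnight home
#' stay, an optional workplace stay, and food-outlet visits whose fast food vs
#' other-food choice follows the home neighborhood's planted propensity.
#' Within each stay, pings are emitted at the configured 5–15 min cadence and
#' jittered with isotropic Gaussian noise whose scale is set so the median
#' radial error equals the configured accuracy. Whole (day, period) blocks are
#' dropped with `period_dropout_prob` to emulate phones going out of service.
#'
#' @param world An `ff_world` from [make_world()].
#' @param config The [world_config()] used to build the world (defaults to the
#'   one stored in `world`).
#' @return Data.frame of pings: `user_id`, `timestamp` (POSIXct, UTC), `lat`,
#'   `lon`, `accuracy_m`, sorted by user and timestamp (strictly increasing
#'   within user). The users' true home assignment is attached as attribute
#'   `"homes"` for validation.
#' @export
simulate_users <- function(world, config = world$config) {
  stopifnot(inherits(world, "ff_world"))
  set.seed(stage_seed(config$seed, "users"))

  nb_ids <- names(world$neighborhoods)
  nb <- length(nb_ids)
  n_users <- config$n_users
  dlat <- km_to_deg_lat(config$grid_cell_km)
  dlon <- km_to_deg_lon(config$grid_cell_km)
  cell_origin <- function(id) {
    i <- match(id, nb_ids)
    ncols <- ceiling(sqrt(nb))
    c(lon = unname(WORLD_ANCHOR["lon"] + ((i - 1) %% ncols) * dlon),
      lat = unname(WORLD_ANCHOR["lat"] + ((i - 1) %/% ncols) * dlat))
  }

  # residential/work anchors are kept clear of POIs (zoning-style separation)
  # so that home and workplace dwells are not spuriously attributed to outlets
  poi_clear_m <- 260
  draw_anchor <- function(nb_id_vec) {
    org <- t(vapply(nb_id_vec, cell_origin, numeric(2)))
    lon <- org[, 1] + stats::runif(length(nb_id_vec), 0.05, 0.95) * dlon
    lat <- org[, 2] + stats::runif(length(nb_id_vec), 0.05, 0.95) * dlat
    for (it in 1:50) {
      nn <- nearest_poi_cpp(lat, lon, world$poi$lat, world$poi$lon, Inf)
      bad <- which(nn$dist_m < poi_clear_m)
      if (length(bad) == 0L) break
      lon[bad] <- org[bad, 1] + stats::runif(length(bad), 0.05, 0.95) * dlon
      lat[bad] <- org[bad, 2] + stats::runif(length(bad), 0.05, 0.95) * dlat
    }
    cbind(lon = lon, lat = lat)
  }

  # balanced home assignment across neighborhoods
  homes <- data.frame(user_id = sprintf("u%05d", seq_len(n_users)),
                      neighborhood_id = nb_ids[(seq_len(n_users) - 1) %% nb + 1])
  hxy <- draw_anchor(homes$neighborhood_id)
  homes$lon <- hxy[, "lon"]
  homes$lat <- hxy[, "lat"]

  is_worker <- stats::runif(n_users) < config$worker_prob
  work_nb <- sample(nb_ids, n_users, replace = TRUE)
  wxy <- draw_anchor(work_nb)
  work_lon <- wxy[, "lon"]
  work_lat <- wxy[, "lat"]

  prop <- world$truth$neighborhood_ff_propensity
  poi <- world$poi
  ff_by_nb <- split(which(poi$is_ff), poi$neighborhood_id[poi$is_ff])
  food_by_nb <- split(which(poi$is_food & !poi$is_ff),
                      poi$neighborhood_id[poi$is_food & !poi$is_ff])
  all_ff <- which(poi$is_ff)
  all_food <- which(poi$is_food & !poi$is_ff)

  pick_food_poi <- function(nb_id, is_ff_visit) {
    pool <- if (is_ff_visit) ff_by_nb[[nb_id]] else food_by_nb[[nb_id]]
    if (is.null(pool) || length(pool) == 0L)
      pool <- if (is_ff_visit) all_ff else all_food
    if (length(pool) == 0L) return(NA_integer_)
    pool[sample.int(length(pool), 1L)]
  }

  # daily stay template (minutes of local day): home, work, lunch, dinner, home
  stay_rows <- vector("list", n_users)
  for (u in seq_len(n_users)) {
    home_nb <- homes$neighborhood_id[u]
    p_ff <- prop[[home_nb]]
    rows <- vector("list", config$days)
    for (d in seq_len(config$days)) {
      st <- list(c(0, 510, homes$lat[u], homes$lon[u]))          # 00:00-08:30
      if (is_worker[u]) {
        st <- c(st, list(c(540, 745, work_lat[u], work_lon[u]))) # 09:00-12:25
      } else if (stats::runif(1) < config$visit_probs[[1]]) {    # morning visit
        j <- pick_food_poi(home_nb, stats::runif(1) < p_ff)
        if (!is.na(j)) st <- c(st, list(c(565, 600, poi$lat[j], poi$lon[j])))
      }
      if (stats::runif(1) < config$visit_probs[[2]]) {           # lunch visit
        j <- pick_food_poi(home_nb, stats::runif(1) < p_ff)
        if (!is.na(j)) st <- c(st, list(c(760, 800, poi$lat[j], poi$lon[j])))
      }
      if (is_worker[u])
        st <- c(st, list(c(815, 990, work_lat[u], work_lon[u]))) # 13:35-16:30
      if (stats::runif(1) < config$visit_probs[[3]]) {           # dinner visit
        j <- pick_food_poi(home_nb, stats::runif(1) < p_ff)
        if (!is.na(j)) st <- c(st, list(c(1110, 1150, poi$lat[j], poi$lon[j])))
      }
      st <- c(st, list(c(1210, 1439, homes$lat[u], homes$lon[u])))
      m <- do.call(rbind, st)
      rows[[d]] <- cbind(day = d, m)
    }
    m <- do.call(rbind, rows)
    stay_rows[[u]] <- cbind(user = u, m)
  }
  sched <- do.call(rbind, stay_rows)
  colnames(sched) <- c("user", "day", "start_min", "end_min", "lat", "lon")

  # pings within each scheduled stay at a per-stay cadence
  iv <- stats::runif(nrow(sched), config$ping_interval_min_range[1],
                     config$ping_interval_min_range[2])
  n_pings <- pmax(1L, floor((sched[, "end_min"] - sched[, "start_min"]) / iv) + 1L)
  rep_idx <- rep(seq_len(nrow(sched)), n_pings)
  within <- sequence(n_pings) - 1L
  t_min <- sched[rep_idx, "start_min"] + within * iv[rep_idx]

  sigma_m <- config$ping_accuracy_median_m / sqrt(2 * log(2))
  lat <- sched[rep_idx, "lat"] +
    stats::rnorm(length(rep_idx), 0, km_to_deg_lat(sigma_m / 1000))
  lon <- sched[rep_idx, "lon"] +
    stats::rnorm(length(rep_idx), 0, km_to_deg_lon(sigma_m / 1000))

  day <- sched[rep_idx, "day"]
  user <- sched[rep_idx, "user"]
  # local datetime -> UTC
  local_s <- (as.numeric(config$start_date - as.Date("1970-01-01")) +
                (day - 1)) * 86400 + t_min * 60
  ts <- .POSIXct(local_s - config$tz_offset_hours * 3600, tz = "UTC")

  pings <- data.table::data.table(
    user_id = sprintf("u%05d", user), timestamp = ts, lat = lat, lon = lon,
    accuracy_m = stats::rlnorm(length(user),
                               log(max(config$ping_accuracy_median_m, 1e-9)),
                               0.35),
    day = day, period = findInterval(t_min / 60, c(11, 16)))

  # whole (day, period) dropout per user
  if (config$period_dropout_prob > 0) {
    blocks <- unique(pings[, c("user_id", "day", "period")])
    blocks[, keep := stats::runif(.N) >= config$period_dropout_prob]
    pings <- merge(pings, blocks, by = c("user_id", "day", "period"))
    pings <- pings[keep == TRUE]
    pings[, keep := NULL]
  }

  data.table::setorder(pings, user_id, timestamp)
  pings[, c("day", "period") := NULL]
  out <- as.data.frame(pings)
  attr(out, "homes") <- homes[, c("user_id", "neighborhood_id")]
  out
}

#' Simulate the health survey
#'
#' Draws respondents with categorical demographics, a residential tract (and
#' hence neighborhood), a four-level fast food intake frequency from a
#' multinomial-logit model on the scaled true neighborhood exposure (10 ×
#' planted propensity), and obesity/diabetes from logistic models with the
#' planted coefficients. A configurable fraction of records receive missing
#' residence or missing study variables, and a small fraction are flagged
#' rural, to exercise the exclusion rules.
#'
#' @param world An `ff_world`.
#' @param truth Planted truth (defaults to the world's own).
#' @param config The [world_config()].
#' @return Data.frame of respondents.
#' @export
simulate_survey <- function(world, truth = world$truth,
                            config = world$config) {
  stopifnot(inherits(world, "ff_world"))
  set.seed(stage_seed(config$seed, "survey"))
  n <- config$n_respondents

  age_levels <- c("18-24", "25-29", "30-39", "40-49", "50-59", "60-64", "65+")
  race_levels <- c("White", "Hispanic/Latino", "Black/African American",
                   "Asian", "Multiracial/other")
  edu_levels <- c("Less than high school", "High school",
                  "Some college or trade school", "College or post graduate")

  tract_ids <- names(world$tracts)
  tract <- sample(tract_ids, n, replace = TRUE)
  nbid <- world$tract_neighborhood[tract]
  s <- 10 * truth$neighborhood_ff_propensity[nbid]   # scaled true exposure

  d <- data.frame(
    id = sprintf("R%05d", seq_len(n)),
    age_group = sample(age_levels, n, replace = TRUE,
                       prob = c(7.4, 5.5, 15.0, 19.9, 20.8, 9.3, 22.2)),
    gender = sample(c("Female", "Male"), n, replace = TRUE,
                    prob = c(60.5, 39.5)),
    race_ethnicity = sample(race_levels, n, replace = TRUE,
                            prob = c(43.4, 35.2, 10.0, 9.3, 2.2)),
    education = sample(edu_levels, n, replace = TRUE,
                       prob = c(17.4, 17.2, 25.2, 40.2)),
    income = sample(c("High", "Low"), n, replace = TRUE, prob = c(62.9, 37.1)),
    neighborhood_id = unname(nbid),
    tract_id = tract,
    rural = stats::runif(n) < config$rural_prob)

  # four-level intake from the planted multinomial logit
  ic <- truth$intake_coefficients
  eta <- cbind(never = 0,
               sapply(names(ic$slopes), function(k)
                 ic$intercepts[[k]] + ic$slopes[[k]] * s))
  p <- exp(eta) / rowSums(exp(eta))
  d$ff_intake <- factor(
    apply(p, 1L, function(pr) sample(colnames(p), 1L, prob = pr)),
    levels = c("never", "infrequent", "moderate", "frequent"))

  draw_disease <- function(cf) {
    eta <- cf[["intercept"]] + cf[["exposure"]] * s +
      cf[["age65"]] * (d$age_group == "65+") +
      cf[["low_income"]] * (d$income == "Low")
    as.integer(stats::runif(n) < stats::plogis(eta))
  }
  d$obesity <- draw_disease(truth$disease_coefficients$obesity)
  d$diabetes <- draw_disease(truth$disease_coefficients$diabetes)

  # planted missingness: residence, then one study variable for a fraction
  miss_res <- stats::runif(n) < config$missing_residence_prob
  d$neighborhood_id[miss_res] <- NA
  d$tract_id[miss_res] <- NA
  d$rural[miss_res] <- NA
  study_vars <- c("age_group", "gender", "race_ethnicity", "education",
                  "income", "ff_intake", "obesity", "diabetes")
  miss_var <- which(stats::runif(n) < config$missing_var_prob)
  if (length(miss_var)) {
    which_var <- sample(study_vars, length(miss_var), replace = TRUE)
    for (i in seq_along(miss_var)) d[miss_var[i], which_var[i]] <- NA
  }
  d
}

#' Simulate tract demographic tables for two years
#'
#' Produces two tables of three percentage variables per tract (share of the
#' population above 200% of the FPL, share Black or African American, share
#' Hispanic or Latino). Non-outlier tracts change between years by centered
#' Gaussian noise with the configured SDs; planted outlier tracts shift by
#' `tract_outlier_shift` points in every variable. All values are clipped to
#' [0, 100].
#'
#' @param world An `ff_world`.
#' @param truth Planted truth (supplies the outlier tract ids).
#' @param config The [world_config()].
#' @return List with data.frames `yearA` and `yearB` (columns `tract_id`,
#'   `pct_above_200fpl`, `pct_black`, `pct_hispanic`).
#' @export
simulate_tract_demographics <- function(world, truth = world$truth,
                                        config = world$config) {
  stopifnot(inherits(world, "ff_world"))
  set.seed(stage_seed(config$seed, "tracts"))
  ids <- names(world$tracts)
  n <- length(ids)
  yearA <- data.frame(tract_id = ids,
                      pct_above_200fpl = stats::runif(n, 30, 90),
                      pct_black = stats::runif(n, 2, 40),
                      pct_hispanic = stats::runif(n, 10, 80))
  sds <- config$tract_change_sd
  shift <- (ids %in% truth$outlier_tracts) * config$tract_outlier_shift
  yearB <- yearA
  for (k in 1:3) {
    v <- c("pct_above_200fpl", "pct_black", "pct_hispanic")[k]
    yearB[[v]] <- pmin(100, pmax(0, yearA[[v]] + stats::rnorm(n, 0, sds[[k]]) +
                                   shift))
  }
  list(yearA = yearA, yearB = yearB)
}
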