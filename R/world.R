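#' Synthetic world configuration
#'
#' Parameters of the synthetic study region, mobility panel, and health survey
#' used for end-to-end validation of the pipeline. Ping cadence (5–15 min),
#' median horizontal accuracy (21 m), and the planted effect magnitudes follow
#' the observed characteristics of large commercial smartphone mobility feeds
#' and diet-survey effect sizes; panel size and observation length default to a
#' scaled-down world that preserves those characteristics.
#'
#' @param n_neighborhoods Number of neighborhoods (grid cells); at least 2.
#' @param grid_cell_km Side length of each neighborhood cell, km.
#' @param n_tracts_per_neighborhood Census-tract-like subdivisions per cell.
#' @param n_poi_per_neighborhood Points of interest per neighborhood.
#' @param ff_fraction_range Range (min, max) of the fraction of each
#'   neighborhood's food POIs that are fast food outlets.
#' @param n_users Smartphone users in the mobility panel.
#' @param n_respondents Health-survey respondents.
#' @param days Days of mobility observation.
#' @param ping_interval_min_range Range of the within-stay ping interval, min.
#' @param ping_accuracy_median_m Median horizontal positional error, m.
#' @param period_dropout_prob Probability that a whole (day, period) block of
#'   pings is unobserved for a user.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param food_fraction Fraction of POIs that sell food.
#' @param ff_propensity_range Range of the planted per-neighborhood
#'   probability that a user's food visit is to a fast food outlet;
#'   neighborhoods are linearly spaced across it.
#' @param intake_or Planted odds ratios per scaled-exposure unit for
#'   infrequent/moderate/frequent intake vs never.
#' @param obesity_or,diabetes_or Planted odds ratios per scaled-exposure unit.
#' @param rural_prob,missing_residence_prob,missing_var_prob Probabilities
#'   driving the survey exclusion rules.
#' @param tract_change_sd Per-variable SD (percentage points) of the
#'   year-over-year demographic change of non-outlier tracts, for the
#'   income (above 200% FPL), Black, and Hispanic percentages; defaults are
#'   calibrated so 95% of tracts move by less than 16, 10, and 15 points.
#' @param tract_outlier_shift Demographic shift (points) planted in outlier
#'   tracts.
#' @param n_outlier_tracts Number of planted outlier tracts.
#' @param visit_probs Daily probabilities of a food-outlet visit in the
#'   morning (non-workers only), lunch, and dinner slots.
#' @param worker_prob Probability a user has a weekday workplace stay.
#' @param tz_offset_hours Fixed local-time offset from UTC, hours.
#' @param start_date First local calendar date of observation.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_neighborhoods = 12,
                         grid_cell_km = 2,
                         n_tracts_per_neighborhood = 4,
                         n_poi_per_neighborhood = 30,
                         ff_fraction_range = c(0.05, 0.30),
                         n_users = 600,
                         n_respondents = 2000,
                         days = 28,
                         ping_interval_min_range = c(5, 15),
                         ping_accuracy_median_m = 21,
                         period_dropout_prob = 0.3,
                         seed = 1L,
                         food_fraction = 0.5,
                         ff_propensity_range = c(0.05, 0.35),
                         intake_or = c(infrequent = 1.13, moderate = 1.26,
                                       frequent = 1.35),
                         obesity_or = 1.16,
                         diabetes_or = 1.15,
                         rural_prob = 104 / 8036,
                         missing_residence_prob = 2007 / 8036,
                         missing_var_prob = 0.08,
                         tract_change_sd = c(fpl = 16, black = 10,
                                             hispanic = 15) / stats::qnorm(0.975),
                         tract_outlier_shift = 30,
                         n_outlier_tracts = 2,
                         visit_probs = c(morning = 0.15, lunch = 0.45,
                                         dinner = 0.45),
                         worker_prob = 0.7,
                         tz_offset_hours = -8,
                         start_date = as.Date("2016-10-01")) {
  cfg <- list(n_neighborhoods = as.integer(n_neighborhoods),
              grid_cell_km = grid_cell_km,
              n_tracts_per_neighborhood = as.integer(n_tracts_per_neighborhood),
              n_poi_per_neighborhood = as.integer(n_poi_per_neighborhood),
              ff_fraction_range = ff_fraction_range,
              n_users = as.integer(n_users),
              n_respondents = as.integer(n_respondents),
              days = as.integer(days),
              ping_interval_min_range = ping_interval_min_range,
              ping_accuracy_median_m = ping_accuracy_median_m,
              period_dropout_prob = period_dropout_prob,
              seed = as.integer(seed),
              food_fraction = food_fraction,
              ff_propensity_range = ff_propensity_range,
              intake_or = intake_or,
              obesity_or = obesity_or,
              diabetes_or = diabetes_or,
              rural_prob = rural_prob,
              missing_residence_prob = missing_residence_prob,
              missing_var_prob = missing_var_prob,
              tract_change_sd = tract_change_sd,
              tract_outlier_shift = tract_outlier_shift,
              n_outlier_tracts = as.integer(n_outlier_tracts),
              visit_probs = visit_probs,
              worker_prob = worker_prob,
              tz_offset_hours = tz_offset_hours,
              start_date = as.Date(start_date))
  with(cfg, {
    stopifnot(n_neighborhoods > 0, n_tracts_per_neighborhood > 0,
              n_poi_per_neighborhood > 0, n_users > 0, n_respondents > 0,
              days > 0,
              period_dropout_prob >= 0, period_dropout_prob <= 1,
              length(ff_fraction_range) == 2,
              all(ff_fraction_range >= 0), all(ff_fraction_range <= 1),
              ff_fraction_range[1] <= ff_fraction_range[2],
              all(ff_propensity_range >= 0), all(ff_propensity_range <= 1),
              ping_interval_min_range[1] <= ping_interval_min_range[2],
              ping_accuracy_median_m >= 0)
  })
  structure(cfg, class = "world_config")
}

# deterministic per-stage seed derived from the master seed
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 2654435 + sum(utf8ToInt(stage)) * 97) %%
               2147483111)
}

# grid anchor (an LA-like latitude so degree/km conversion is realistic)
WORLD_ANCHOR <- c(lat = 34.0, lon = -118.4)

km_to_deg_lat <- function(km) km / 110.574
km_to_deg_lon <- function(km, lat = WORLD_ANCHOR["lat"]) {
  km / (111.320 * cos(lat * pi / 180))
}

# default validated chain-brand list used to label fast food outlets
#' Default fast food chain brand list
#'
#' A list of national limited-service chain brands used both to name the
#' synthetic fast food POIs and to classify them downstream.
#'
#' @return Character vector of brand names.
#' @export
default_ff_brands <- function() {
  c("McDonald's", "Taco Bell", "Pizza Hut", "Burger King", "KFC", "Subway",
    "Wendy's", "Jack in the Box", "Carl's Jr", "Domino's Pizza", "Popeyes",
    "Del Taco", "Panda Express", "In-N-Out Burger", "Chick-fil-A")
}

FOOD_CATEGORIES <- c("Fast Food Restaurant", "Restaurant", "Cafe",
                     "Grocery Store")
NONFOOD_CATEGORIES <- c("Park", "Office", "Retail", "Gym")

#' Generate the synthetic study region
#'
#' Builds a rectangular grid of non-overlapping neighborhood polygons (each
#' subdivided into tract polygons), scatters POIs inside the neighborhoods,
#' labels a planted subset of food POIs as fast food outlets, and returns the
#' planted ground truth (per-neighborhood fast food visit propensities,
#' outcome-model coefficients, and the identity of demographic outlier
#' tracts). Deterministic given the config seed.
#'
#' @param config A [world_config()].
#' @return An object of class `ff_world`: list with elements `neighborhoods`
#'   and `tracts` (polygon sets), `poi` (data.frame), `truth` (planted
#'   parameters), `tract_neighborhood` (named id map), and `config`.
#' @export
make_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  if (config$n_neighborhoods < 2)
    stop("aggregation needs at least 2 neighborhoods")
  set.seed(stage_seed(config$seed, "world"))

  nb <- config$n_neighborhoods
  ncols <- ceiling(sqrt(nb))
  nrows <- ceiling(nb / ncols)
  dlat <- km_to_deg_lat(config$grid_cell_km)
  dlon <- km_to_deg_lon(config$grid_cell_km)

  nb_ids <- sprintf("N%02d", seq_len(nb))
  neighborhoods <- list()
  tracts <- list()
  tract_neighborhood <- character(0)
  cells <- data.frame(id = nb_ids, row = (seq_len(nb) - 1) %/% ncols,
                      col = (seq_len(nb) - 1) %% ncols)
  for (i in seq_len(nb)) {
    lon0 <- WORLD_ANCHOR["lon"] + cells$col[i] * dlon
    lat0 <- WORLD_ANCHOR["lat"] + cells$row[i] * dlat
    neighborhoods[[nb_ids[i]]] <- cbind(
      lon = c(lon0, lon0 + dlon, lon0 + dlon, lon0),
      lat = c(lat0, lat0, lat0 + dlat, lat0 + dlat))
    nt <- config$n_tracts_per_neighborhood
    for (k in seq_len(nt)) {
      tid <- sprintf("%s_T%02d", nb_ids[i], k)
      tl <- lon0 + (k - 1) * dlon / nt
      tracts[[tid]] <- cbind(lon = c(tl, tl + dlon / nt, tl + dlon / nt, tl),
                             lat = c(lat0, lat0, lat0 + dlat, lat0 + dlat))
      tract_neighborhood[tid] <- nb_ids[i]
    }
  }
  class(neighborhoods) <- "polygon_set"
  class(tracts) <- "polygon_set"

  # POIs: uniform within each neighborhood with a small inset so every POI is
  # inside exactly one cell
  propensity <- stats::setNames(
    seq(config$ff_propensity_range[1], config$ff_propensity_range[2],
        length.out = nb), nb_ids)
  brands <- default_ff_brands()
  poi_list <- vector("list", nb)
  for (i in seq_len(nb)) {
    np <- config$n_poi_per_neighborhood
    lon0 <- WORLD_ANCHOR["lon"] + cells$col[i] * dlon
    lat0 <- WORLD_ANCHOR["lat"] + cells$row[i] * dlat
    lon <- lon0 + stats::runif(np, 0.02, 0.98) * dlon
    lat <- lat0 + stats::runif(np, 0.02, 0.98) * dlat
    n_food <- round(np * config$food_fraction)
    ff_frac <- stats::runif(1, config$ff_fraction_range[1],
                            config$ff_fraction_range[2])
    n_ff <- round(n_food * ff_frac)
    is_food <- c(rep(TRUE, n_food), rep(FALSE, np - n_food))
    is_ff <- c(rep(TRUE, n_ff), rep(FALSE, np - n_ff))
    category <- ifelse(is_ff, "Fast Food Restaurant",
                       ifelse(is_food,
                              sample(setdiff(FOOD_CATEGORIES,
                                             "Fast Food Restaurant"),
                                     np, replace = TRUE),
                              sample(NONFOOD_CATEGORIES, np, replace = TRUE)))
    idx <- seq_len(np) + (i - 1) * np
    name <- ifelse(is_ff,
                   paste0(sample(brands, np, replace = TRUE), " #", idx),
                   paste(category, idx))
    poi_list[[i]] <- data.frame(
      poi_id = sprintf("P%05d", idx), name = name, lat = lat, lon = lon,
      category = category, is_food = is_food, is_ff = is_ff,
      neighborhood_id = nb_ids[i])
  }
  poi <- do.call(rbind, poi_list)
  rownames(poi) <- NULL

  # planted outcome-model coefficients; intercepts anchored so that at the
  # mid-range exposure the outcome mix matches typical urban survey margins
  s_ref <- 10 * mean(config$ff_propensity_range)
  intake_slopes <- log(config$intake_or)
  target_mix <- c(never = 0.173, infrequent = 0.191, moderate = 0.269,
                  frequent = 0.367)
  intake_intercepts <- log(target_mix[-1] / target_mix[1]) -
    intake_slopes * s_ref
  names(intake_intercepts) <- names(intake_slopes)

  disease <- list(
    obesity = c(intercept = unname(stats::qlogis(0.248) -
                                     log(config$obesity_or) * s_ref),
                exposure = unname(log(config$obesity_or)),
                age65 = log(1.2), low_income = log(1.3)),
    diabetes = c(intercept = unname(stats::qlogis(0.111) -
                                      log(config$diabetes_or) * s_ref),
                 exposure = unname(log(config$diabetes_or)),
                 age65 = log(1.5), low_income = log(1.3)))

  outlier_tracts <- sort(sample(names(tracts),
                                min(config$n_outlier_tracts, length(tracts))))

  truth <- list(neighborhood_ff_propensity = propensity,
                intake_coefficients = list(intercepts = intake_intercepts,
                                           slopes = intake_slopes),
                disease_coefficients = disease,
                outlier_tracts = outlier_tracts)

  structure(list(neighborhoods = neighborhoods, tracts = tracts, poi = poi,
                 truth = truth, tract_neighborhood = tract_neighborhood,
                 config = config),
            class = "ff_world")
}

#' @export
print.ff_world <- function(x, ...) {
  cat("Synthetic study region:",
      length(x$neighborhoods), "neighborhoods,",
      length(x$tracts), "tracts,",
      nrow(x$poi), "POI (",
      sum(x$poi$is_food), "food /", sum(x$poi$is_ff), "fast food )\n")
  cat("Planted FF propensity range:",
      sprintf("%.2f-%.2f", min(x$truth$neighborhood_ff_propensity),
              max(x$truth$neighborhood_ff_propensity)), "\n")
  invisible(x)
}
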