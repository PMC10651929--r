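# survey-only fixtures used across the model and sensitivity tests

# respondents drawn from a world with no planted missingness; exposure is the
# scaled true neighborhood propensity
survey_fixture <- function(n = 3000, seed = 71, ...) {
  cfg <- world_config(n_respondents = n, missing_residence_prob = 0,
                      missing_var_prob = 0, rural_prob = 0, seed = seed, ...)
  w <- make_world(cfg)
  d <- simulate_survey(w, w$truth, cfg)
  d$exposure <- 10 * w$truth$neighborhood_ff_propensity[d$neighborhood_id]
  list(data = d, world = w)
}


# shared analytic fixture with homogeneous planted effects and true-scale
# contextual exposures
analytic_fixture <- function(n = 6000, seed = 84) {
  cfg <- world_config(n_neighborhoods = 16, n_respondents = n,
                      missing_residence_prob = 0, missing_var_prob = 0,
                      rural_prob = 0, seed = seed)
  w <- make_world(cfg)
  d <- simulate_survey(w, w$truth, cfg)
  s <- 10 * w$truth$neighborhood_ff_propensity[d$neighborhood_id]
  d$scaled_ff_food <- unname(s)
  d$scaled_ff_time <- unname(0.4 * s)
  # trips/day varies across neighborhoods independently of FF exposure
  set.seed(seed + 1)
  tpd <- stats::setNames(runif(16, 2.2, 8), names(w$truth$neighborhood_ff_propensity))
  d$scaled_trips_day <- unname(tpd[d$neighborhood_id])
  list(data = d, world = w)
}

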