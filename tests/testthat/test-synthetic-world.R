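small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_neighborhoods = 4, n_poi_per_neighborhood = 10, n_users = 24,
         n_respondents = 200, days = 5, seed = 5),
    list(...))
  do.call(world_config, args)
}

test_that("world geometry and POI counts follow the config", {
  w <- make_world(small_cfg())
  expect_equal(nrow(w$poi), 40L)
  expect_length(w$neighborhoods, 4L)
  expect_length(w$tracts, 16L)
  # each POI inside exactly one neighborhood, and it is the labelled one
  hits <- vapply(seq_len(nrow(w$poi)), function(i)
    sum(vapply(names(w$neighborhoods), function(id)
      mgcv::in.out(w$neighborhoods[[id]],
                   cbind(w$poi$lon[i], w$poi$lat[i])), logical(1))),
    integer(1))
  expect_true(all(hits == 1L))
  loc <- locate_points(w$poi$lon, w$poi$lat, w$neighborhoods)
  expect_equal(loc, w$poi$neighborhood_id)
  expect_true(all(w$poi$is_food[w$poi$is_ff]))
})

test_that("generation is deterministic given the seed", {
  cfg <- small_cfg()
  w1 <- make_world(cfg); w2 <- make_world(cfg)
  expect_identical(w1, w2)
  expect_identical(simulate_users(w1), simulate_users(w2))
  expect_identical(simulate_survey(w1), simulate_survey(w2))
  expect_identical(simulate_tract_demographics(w1),
                   simulate_tract_demographics(w2))
  w3 <- make_world(small_cfg(seed = 6))
  expect_false(identical(w1$poi$lat, w3$poi$lat))
})

test_that("a degenerate fast food fraction is honored exactly", {
  w <- make_world(small_cfg(ff_fraction_range = c(0.2, 0.2)))
  per_nb <- table(w$poi$neighborhood_id[w$poi$is_ff])
  n_food <- table(w$poi$neighborhood_id[w$poi$is_food])
  expect_true(all(as.integer(per_nb) == round(as.integer(n_food) * 0.2)))
})

test_that("fewer than two neighborhoods is rejected", {
  expect_error(make_world(world_config(n_neighborhoods = 1)), "2")
})

test_that("total period dropout empties the ping stream", {
  w <- make_world(small_cfg(period_dropout_prob = 1))
  expect_equal(nrow(simulate_users(w)), 0L)
})

test_that("with zero noise and no outings all pings sit at the home anchor", {
  cfg <- small_cfg(ping_accuracy_median_m = 0, worker_prob = 0,
                   visit_probs = c(0, 0, 0), period_dropout_prob = 0,
                   days = 2, n_users = 4)
  w <- make_world(cfg)
  pings <- simulate_users(w, cfg)
  homes <- attr(pings, "homes")
  expect_gt(nrow(pings), 0)
  for (u in homes$user_id) {
    pu <- pings[pings$user_id == u, ]
    expect_equal(length(unique(pu$lat)), 1L)
    expect_equal(length(unique(pu$lon)), 1L)
  }
  # timestamps strictly increasing per user
  by_user <- split(as.numeric(pings$timestamp), pings$user_id)
  expect_true(all(vapply(by_user, function(x) all(diff(x) > 0), logical(1))))
})

test_that("median radial ping error matches the configured accuracy", {
  cfg <- small_cfg(worker_prob = 0, visit_probs = c(0, 0, 0),
                   period_dropout_prob = 0, n_users = 50, days = 3)
  w <- make_world(cfg)
  pings <- simulate_users(w, cfg)
  homes <- attr(pings, "homes")
  # recover each user's anchor as the coordinate-wise median of their pings
  err <- unlist(lapply(split(pings, pings$user_id), function(pu) {
    oracle_dist_m(pu$lon, pu$lat, median(pu$lon), median(pu$lat))
  }))
  expect_equal(median(err), 21, tolerance = 0.1)
})

test_that("null intake coefficients reproduce the intercept-implied mix", {
  cfg <- small_cfg(intake_or = c(infrequent = 1, moderate = 1, frequent = 1),
                   n_respondents = 4000, missing_var_prob = 0)
  w <- make_world(cfg)
  d <- simulate_survey(w, w$truth, cfg)
  freq <- prop.table(table(d$ff_intake))
  target <- c(never = 0.173, infrequent = 0.191, moderate = 0.269,
              frequent = 0.367)
  expect_true(all(abs(freq - target) < 3 * sqrt(target * (1 - target) / 4000)
                  + 0.005))
})

test_that("without planted missingness only rural exclusions remain", {
  cfg <- small_cfg(missing_residence_prob = 0, missing_var_prob = 0)
  w <- make_world(cfg)
  d <- simulate_survey(w, w$truth, cfg)
  ex <- apply_exclusions(d)
  expect_equal(unname(ex$counts["missing_residence"]), 0L)
  expect_equal(unname(ex$counts["missing_variable"]), 0L)
  expect_equal(nrow(ex$analytic), nrow(d) - sum(d$rural))
})

test_that("tract tables are stable unless change is planted", {
  cfg <- small_cfg(tract_change_sd = c(0, 0, 0), n_outlier_tracts = 0)
  w <- make_world(cfg)
  demo <- simulate_tract_demographics(w, w$truth, cfg)
  expect_equal(demo$yearA, demo$yearB)

  cfg2 <- small_cfg(tract_change_sd = c(0, 0, 0), n_outlier_tracts = 1,
                    tract_outlier_shift = 30)
  w2 <- make_world(cfg2)
  demo2 <- simulate_tract_demographics(w2, w2$truth, cfg2)
  ch <- tract_changes(demo2$yearA, demo2$yearB)
  moved <- ch$tract_id[abs(ch$delta_black) > 0]
  expect_equal(moved, w2$truth$outlier_tracts)
})

test_that("95% of non-outlier tracts change less than the calibration bounds", {
  cfg <- world_config(n_neighborhoods = 25, n_tracts_per_neighborhood = 40,
                      n_outlier_tracts = 0, seed = 9)
  w <- make_world(cfg)
  demo <- simulate_tract_demographics(w, w$truth, cfg)
  ch <- tract_changes(demo$yearA, demo$yearB)
  # defaults place the 95% absolute-change quantile at 16/10/15 points
  expect_equal(stability_quantile(ch, "delta_fpl"), 16, tolerance = 0.1)
  expect_equal(stability_quantile(ch, "delta_black"), 10, tolerance = 0.12)
  expect_equal(stability_quantile(ch, "delta_hispanic"), 15, tolerance = 0.1)
})
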