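# all fixtures below use local time = UTC (tz offset 0)

test_that("observed periods come from stay start times", {
  one <- make_stays(9)
  op <- observed_periods(one, tz_offset_hours = 0)
  expect_equal(op$period, 0L)
  op3 <- observed_periods(make_stays(c(9, 12, 20)), tz_offset_hours = 0)
  expect_equal(nrow(op3), 3L)
  expect_equal(sort(op3$period), 0:2)
  expect_equal(nrow(observed_periods(make_stays(numeric(0)))), 0L)
})

test_that("period boundaries are half-open at 11:00 and 16:00", {
  op <- observed_periods(make_stays(c(10.99, 11, 15.99, 16), dur_min = 1),
                         tz_offset_hours = 0)
  expect_equal(sort(op$period), c(0L, 1L, 2L))  # 11 and 15.99 share period 1
})

test_that("FF visits/time counts periods with at least one FF stay", {
  days <- rep(as.Date("2016-10-01") + 0:4, each = 2)
  st <- do.call(rbind, Map(function(h, d) make_stays(h, day0 = d),
                           rep(c(9, 12), 5), days))
  st$is_ff <- FALSE; st$is_food <- FALSE
  st$is_ff[1] <- st$is_food[1] <- TRUE
  expect_equal(ff_visits_time(st, tz_offset_hours = 0), 10)
  st$is_ff[] <- FALSE
  expect_equal(ff_visits_time(st, tz_offset_hours = 0), 0)
  expect_true(is.na(ff_visits_time(st[0, ], tz_offset_hours = 0)))
})

test_that("FF visits/time is invariant to duplicating a stay in an FF period", {
  st <- make_stays(c(9, 12, 18), is_ff = c(TRUE, FALSE, FALSE))
  base <- ff_visits_time(st, tz_offset_hours = 0)
  dup <- rbind(st, st[1, ])
  dup <- dup[order(dup$start), ]
  expect_equal(ff_visits_time(dup, tz_offset_hours = 0), base)
})

test_that("FF visits/time equals direct enumeration over (date, period)", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(3:40, 1)
    st <- make_stays(runif(n, 0, 23.9),
                     day0 = as.Date("2016-10-01") + sample(0:6, n, TRUE),
                     is_ff = runif(n) < 0.3)
    st <- st[order(st$start), ]
    hrs <- as.numeric(format(st$start, "%H")) +
      as.numeric(format(st$start, "%M")) / 60
    per <- findInterval(hrs, c(11, 16))
    key <- paste(as.Date(st$start), per)
    want <- 100 * length(unique(key[st$is_ff])) / length(unique(key))
    expect_equal(ff_visits_time(st, tz_offset_hours = 0), want)
  }
})

test_that("FF visits/food is the fast food share of food visits", {
  st <- make_stays(seq(1, 23, length.out = 20),
                   is_food = TRUE, is_ff = rep(c(TRUE, FALSE), c(2, 18)))
  expect_equal(ff_visits_food(st), 10)
  expect_equal(ff_visits_food(transform(st, is_ff = TRUE)), 100)
  expect_equal(ff_visits_food(transform(st, is_ff = FALSE)), 0)
  expect_true(is.na(ff_visits_food(transform(st, is_food = FALSE,
                                             is_ff = FALSE))))
})

test_that("trips per day divides trips by observation days", {
  two_days <- rbind(make_stays(seq(8, 16, 2)),
                    make_stays(seq(8, 14, 2), day0 = as.Date("2016-10-02")))
  expect_equal(count_trips(two_days), 8L)
  expect_equal(trips_per_day(two_days, tz_offset_hours = 0), 4)
  expect_equal(trips_per_day(make_stays(9), tz_offset_hours = 0), 0)
  expect_equal(trips_per_day(make_stays(c(8, 10, 12, 14, 16)),
                             tz_offset_hours = 0), 4)
})

test_that("home inference follows nighttime dwell duration", {
  w <- make_world(world_config(n_neighborhoods = 4, seed = 51))
  nb <- w$neighborhoods
  center <- function(id) colMeans(nb[[id]])
  a <- center("N01"); b <- center("N02")
  # 6 h overnight in N01 vs 1 h late evening in N02
  st <- data.frame(
    start = as.POSIXct(c("2016-10-01 23:00:00", "2016-10-01 21:30:00"),
                       tz = "UTC"),
    end = as.POSIXct(c("2016-10-02 05:00:00", "2016-10-01 23:00:00"),
                     tz = "UTC"),
    centroid_lat = c(a["lat"], b["lat"]),
    centroid_lon = c(a["lon"], b["lon"]), n_pings = 2L)
  expect_equal(infer_home(st, nb, tz_offset_hours = 0), "N01")
  # a user with no nighttime activity is flagged
  day_only <- make_stays(c(10, 14), lat = a["lat"], lon = a["lon"])
  expect_true(is.na(infer_home(day_only, nb, tz_offset_hours = 0)))
})

test_that("home inference matches a brute-force nighttime tally", {
  set.seed(52)
  w <- make_world(world_config(n_neighborhoods = 6, seed = 52))
  nb <- w$neighborhoods
  centers <- t(vapply(nb, colMeans, numeric(2)))
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    pick <- sample(length(nb), n, replace = TRUE)
    start <- as.POSIXct("2016-10-01", tz = "UTC") +
      runif(n, 0, 3 * 86400)
    st <- data.frame(start = start, end = start + runif(n, 600, 10 * 3600),
                     centroid_lat = centers[pick, "lat"],
                     centroid_lon = centers[pick, "lon"], n_pings = 2L,
                     nb_id = names(nb)[pick])
    st <- st[order(st$start), ]
    # oracle: per-minute membership in the 22:00-06:00 window
    dur <- vapply(seq_len(nrow(st)), function(i) {
      sec <- seq(as.numeric(st$start[i]), as.numeric(st$end[i]) - 1, by = 60)
      h <- (sec %% 86400) / 3600
      60 * sum(h >= 22 | h < 6)
    }, numeric(1))
    tot <- tapply(dur, st$nb_id, sum)
    if (all(tot == 0)) {
      expect_true(is.na(infer_home(st, nb, tz_offset_hours = 0)))
    } else {
      # minute-resolution tally: treat near-ties (< 5 min apart) as ties
      best <- names(tot)[tot >= max(tot) - 300]
      expect_true(infer_home(st, nb, tz_offset_hours = 0) %in% best)
    }
  }
})

test_that("a world without fast food outlets yields zero FF metrics", {
  cfg <- world_config(n_neighborhoods = 4, n_users = 16, days = 3,
                      ff_fraction_range = c(0, 0), seed = 53)
  w <- make_world(cfg)
  expect_equal(sum(w$poi$is_ff), 0L)
  pings <- simulate_users(w, cfg)
  stays <- detect_stays_by_user(pings)
  att <- attribute_stays(stays, classify_food_outlets(w$poi))
  um <- compute_user_metrics(att, w$neighborhoods,
                             tz_offset_hours = cfg$tz_offset_hours)
  expect_true(all(um$ff_visits_time_pct == 0, na.rm = TRUE))
  expect_true(all(um$ff_visits_food_pct == 0, na.rm = TRUE))
})
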