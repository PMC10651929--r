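# Independent brute-force oracles, written as direct transliterations of the
# operation contracts. They share no code with the package implementations.

# haversine via geosphere with the package's Earth radius
oracle_dist_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371000)
}

# greedy sequential stay clustering in plain R
oracle_detect_stays <- function(pings, d_roam_m = 50, min_duration_min = 5,
                                min_events = 2) {
  stays <- list()
  cluster <- integer(0)
  flush <- function(cluster) {
    if (length(cluster) >= min_events) {
      dur <- as.numeric(difftime(pings$timestamp[cluster[length(cluster)]],
                                 pings$timestamp[cluster[1]], units = "mins"))
      if (dur >= min_duration_min) {
        return(data.frame(
          start = pings$timestamp[cluster[1]],
          end = pings$timestamp[cluster[length(cluster)]],
          centroid_lat = stats::median(pings$lat[cluster]),
          centroid_lon = stats::median(pings$lon[cluster]),
          n_pings = length(cluster)))
      }
    }
    NULL
  }
  for (i in seq_len(nrow(pings))) {
    cand <- c(cluster, i)
    clat <- stats::median(pings$lat[cand])
    clon <- stats::median(pings$lon[cand])
    dmax <- max(oracle_dist_m(pings$lon[cand], pings$lat[cand], clon, clat))
    if (length(cluster) == 0L || dmax < d_roam_m) {
      cluster <- cand
    } else {
      stays[[length(stays) + 1L]] <- flush(cluster)
      cluster <- i
    }
  }
  stays[[length(stays) + 1L]] <- flush(cluster)
  stays <- do.call(rbind, stays)
  if (is.null(stays))
    stays <- data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                        end = as.POSIXct(character(0), tz = "UTC"),
                        centroid_lat = numeric(0), centroid_lon = numeric(0),
                        n_pings = integer(0))
  stays
}

# exhaustive all-pairs nearest-neighbor attribution
oracle_attribute <- function(stays, poi, d_max_m = 200) {
  poi <- poi[order(poi$poi_id), ]
  sapply(seq_len(nrow(stays)), function(i) {
    d <- oracle_dist_m(stays$centroid_lon[i], stays$centroid_lat[i],
                       poi$lon, poi$lat)
    j <- which(d == min(d))[1]          # ties -> smallest poi_id (sorted)
    if (d[j] < d_max_m) poi$poi_id[j] else NA_character_
  })
}

# random ping streams: mixture of tight dwell bursts and scattered jumps so
# cluster boundaries are exercised in both directions
random_pings <- function(n = 50, jump_prob = 0.3, spread_m = 60) {
  t0 <- as.POSIXct("2016-10-01 00:00:00", tz = "UTC")
  lat <- numeric(n); lon <- numeric(n)
  lat[1] <- 34 + runif(1, 0, 0.02); lon[1] <- -118.4 + runif(1, 0, 0.02)
  for (i in 2:n) {
    if (runif(1) < jump_prob) {
      lat[i] <- 34 + runif(1, 0, 0.02)
      lon[i] <- -118.4 + runif(1, 0, 0.02)
    } else {
      lat[i] <- lat[i - 1] + rnorm(1, 0, spread_m / 3 / 110574)
      lon[i] <- lon[i - 1] + rnorm(1, 0, spread_m / 3 / 92000)
    }
  }
  data.frame(timestamp = t0 + cumsum(runif(n, 60, 900)), lat = lat, lon = lon)
}

# simple stay-table constructor for metric tests (times local = UTC offset 0)
make_stays <- function(start_hours, dur_min = 30, lat = 34, lon = -118.4,
                       is_food = FALSE, is_ff = FALSE,
                       day0 = as.Date("2016-10-01")) {
  n <- length(start_hours)
  start <- as.POSIXct(paste(day0), tz = "UTC") + start_hours * 3600
  data.frame(start = start, end = start + dur_min * 60,
             centroid_lat = rep_len(lat, n), centroid_lon = rep_len(lon, n),
             n_pings = rep_len(2L, n),
             is_food = rep_len(is_food, n) | rep_len(is_ff, n),
             is_ff = rep_len(is_ff, n))
}
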