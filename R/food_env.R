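# token-normalized name matching used for brand classification: case-fold,
# strip punctuation, collapse whitespace
normalize_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Classify food and fast food outlets
#'
#' Flags POIs as food outlets when their category belongs to the configured
#' food category set, and as fast food outlets when they are food outlets
#' whose normalized name matches a normalized chain brand. Matching is
#' token-prefix: "McDonald's #1234" matches brand "McDonald's" because the
#' brand's tokens are a prefix of the name's tokens after case-folding and
#' punctuation removal.
#'
#' @param poi Data.frame with at least `name` and `category`.
#' @param food_categories Character set of food category labels.
#' @param ff_brands Character vector of chain brand names; empty list issues a
#'   warning and flags nothing as fast food.
#' @return `poi` with logical columns `is_food` and `is_ff` (re)computed.
#' @export
classify_food_outlets <- function(poi,
                                  food_categories = FOOD_CATEGORIES,
                                  ff_brands = default_ff_brands()) {
  stopifnot(all(c("name", "category") %in% names(poi)))
  poi$is_food <- poi$category %in% food_categories
  if (length(ff_brands) == 0L) {
    warning("empty brand list: no POIs flagged as fast food")
    poi$is_ff <- FALSE
    return(poi)
  }
  norm_names <- normalize_name(poi$name)
  norm_brands <- normalize_name(ff_brands)
  matched <- Reduce(`|`, lapply(norm_brands, function(b) {
    startsWith(norm_names, b) &
      (nchar(norm_names) == nchar(b) |
         substr(norm_names, nchar(b) + 1L, nchar(b) + 1L) == " ")
  }))
  poi$is_ff <- poi$is_food & matched
  poi
}

#' Attribution parameters
#'
#' @param d_max_m Maximum attribution distance in meters; a stay is attributed
#'   to its nearest POI only when that POI lies strictly within this radius.
#' @return Object of class `attribution_params`.
#' @export
attribution_params <- function(d_max_m = 200) {
  stopifnot(d_max_m > 0)
  structure(list(d_max_m = d_max_m), class = "attribution_params")
}

#' Attribute stays to the nearest POI
#'
#' Each stay centroid is matched to the haversine-nearest POI, and attributed
#' to it iff the distance is strictly below `d_max_m`. Ties at equal distance
#' resolve to the smallest `poi_id`.
#'
#' @param stays Data.frame with `centroid_lat`, `centroid_lon`.
#' @param poi POI table with `poi_id`, `lat`, `lon`, `is_food`, `is_ff`.
#' @param params An [attribution_params()].
#' @return `stays` with added columns `poi_id` (NA when unattributed),
#'   `dist_m`, `is_food`, `is_ff`.
#' @export
attribute_stays <- function(stays, poi, params = attribution_params()) {
  stopifnot(inherits(params, "attribution_params"))
  if (nrow(poi) > 0) {
    stopifnot(all(is.finite(poi$lat)), all(is.finite(poi$lon)))
    poi <- poi[order(poi$poi_id), , drop = FALSE]  # tie-break by smallest id
  }
  if (nrow(stays) == 0L || nrow(poi) == 0L) {
    stays$poi_id <- rep(NA_character_, nrow(stays))
    stays$dist_m <- rep(NA_real_, nrow(stays))
    stays$is_food <- rep(FALSE, nrow(stays))
    stays$is_ff <- rep(FALSE, nrow(stays))
    return(stays)
  }
  nn <- nearest_poi_cpp(stays$centroid_lat, stays$centroid_lon,
                        poi$lat, poi$lon, params$d_max_m)
  hit <- nn$index > 0L
  stays$poi_id <- ifelse(hit, poi$poi_id[pmax(nn$index, 1L)], NA_character_)
  stays$dist_m <- nn$dist_m
  stays$is_food <- hit & poi$is_food[pmax(nn$index, 1L)]
  stays$is_ff <- hit & poi$is_ff[pmax(nn$index, 1L)]
  stays
}

#' Share of stays at food outlets
#'
#' Percentage of all stays attributed to a food outlet.
#'
#' @param attributed_stays Output of [attribute_stays()].
#' @return Percentage in [0, 100].
#' @export
food_visit_share <- function(attributed_stays) {
  n <- nrow(attributed_stays)
  if (n == 0L) stop("food_visit_share is undefined for zero stays")
  100 * sum(attributed_stays$is_food) / n
}
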