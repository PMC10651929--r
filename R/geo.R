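#' @useDynLib mobifood, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Earth radius (m) used for every haversine distance in the package, so the
# synthetic generator and the pipeline agree on geometry.
EARTH_RADIUS_M <- 6371000

#' Haversine distance in meters
#'
#' Great-circle distance on WGS84 coordinates with a spherical Earth of radius
#' 6,371,000 m. Vectorized over both point sets.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Numeric vector of distances in meters.
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_M)
}

#' Assign points to polygons
#'
#' Point-in-polygon lookup against a polygon set (as returned by
#' [make_world()] or [read_geojson_polygons()]). Each point receives the id of
#' the first polygon containing it, or `NA` if none does.
#'
#' @param lon,lat Point coordinates in decimal degrees.
#' @param polygons A `polygon_set`: named list of two-column (lon, lat)
#'   vertex matrices, names giving polygon ids.
#' @return Character vector of polygon ids (NA where uncontained).
#' @export
locate_points <- function(lon, lat, polygons) {
  stopifnot(length(lon) == length(lat))
  out <- rep(NA_character_, length(lon))
  if (length(lon) == 0L) return(out)
  pts <- cbind(lon, lat)
  for (id in names(polygons)) {
    todo <- is.na(out)
    if (!any(todo)) break
    inside <- mgcv::in.out(polygons[[id]], pts[todo, , drop = FALSE])
    out[todo][inside] <- id
  }
  out
}

#' Read polygons from a GeoJSON FeatureCollection
#'
#' Reads WGS84 Polygon features (outer ring only) into the package's
#' `polygon_set` representation. The feature property named `id_property`
#' supplies the polygon ids.
#'
#' @param path GeoJSON file path.
#' @param id_property Name of the feature property holding the id.
#' @return Named list of (lon, lat) vertex matrices, class `polygon_set`.
#' @export
read_geojson_polygons <- function(path, id_property = "id") {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  out <- list()
  for (feat in gj$features) {
    id <- as.character(feat$properties[[id_property]])
    ring <- feat$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    out[[id]] <- m
  }
  structure(out, class = "polygon_set")
}

#' Write polygons to a GeoJSON FeatureCollection
#'
#' @param polygons A `polygon_set`.
#' @param path Output file path.
#' @param id_property Property name under which to store ids.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(polygons, path, id_property = "id") {
  feats <- lapply(names(polygons), function(id) {
    m <- polygons[[id]]
    # close the ring if open
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    props <- stats::setNames(list(id), id_property)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(m)),
                                                   function(i) c(m[i, 1], m[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Local clock helpers: "local" time is UTC plus a fixed hour offset (the study
# region's standard time); no DST is modelled.
local_shift <- function(ts, tz_offset_hours) ts + tz_offset_hours * 3600

local_date <- function(ts, tz_offset_hours) {
  as.Date(local_shift(ts, tz_offset_hours), tz = "UTC")
}

local_hour <- function(ts, tz_offset_hours) {
  lt <- as.POSIXlt(local_shift(ts, tz_offset_hours), tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}
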