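#' Read a ping CSV
#'
#' Reads `user_id, timestamp, lat, lon[, accuracy_m]` with ISO-8601 UTC
#' timestamps and returns pings sorted by user and time.
#'
#' @param path CSV path.
#' @return Data.frame of pings.
#' @export
read_pings <- function(path) {
  dt <- data.table::fread(path)
  dt[, timestamp := as.POSIXct(timestamp, tz = "UTC",
                               format = "%Y-%m-%dT%H:%M:%OSZ")]
  data.table::setorder(dt, user_id, timestamp)
  as.data.frame(dt)
}

write_csv_ts <- function(df, path) {
  df <- as.data.frame(df)
  for (cn in names(df))
    if (inherits(df[[cn]], "POSIXct"))
      df[[cn]] <- format(df[[cn]], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  data.table::fwrite(df, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the synthetic world build, mobility simulation, stay
#' detection, POI classification and attribution, per-user metrics,
#' neighborhood aggregation, survey linkage, exclusions, descriptive
#' comparison, the regression models with Akaike-weight comparison, and the
#' sensitivity analyses. When `out_dir` is given, every stage's table is
#' written there along with a machine-readable run manifest.
#'
#' @param config A [world_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param min_users Minimum users per neighborhood retained in aggregation.
#' @return Invisibly, a list of class `ff_pipeline` with all intermediate and
#'   final artifacts.
#' @export
run_pipeline <- function(config = world_config(), out_dir = NULL,
                         min_users = 5) {
  world <- make_world(config)
  pings <- simulate_users(world, config)
  stays <- detect_stays_by_user(pings, stay_params())
  poi <- classify_food_outlets(world$poi)
  attributed <- attribute_stays(stays, poi, attribution_params())
  um <- compute_user_metrics(attributed, world$neighborhoods,
                             tz_offset_hours = config$tz_offset_hours)
  nm <- rescale_metrics(aggregate_by_neighborhood(um, min_users))
  respondents <- simulate_survey(world, world$truth, config)
  linked <- link_to_respondents(respondents, nm)
  excl <- apply_exclusions(linked)
  analytic <- excl$analytic[excl$analytic$linked, , drop = FALSE]
  table1 <- compare_samples(respondents, analytic)

  exposures <- c("scaled_ff_time", "scaled_ff_food")
  fits <- list()
  for (ex in exposures) {
    fits[[paste0("intake~", ex)]] <- fit_multinomial(analytic, ex,
                                                     adjusted = FALSE)
    fits[[paste0("intake~", ex, "+cov")]] <- fit_multinomial(analytic, ex,
                                                             adjusted = TRUE)
  }
  for (outc in c("obesity", "diabetes")) {
    for (ex in c(exposures, "ff_intake"))
      fits[[paste0(outc, "~", ex)]] <- fit_binary(analytic, outc, ex)
  }
  akaike <- lapply(c(obesity = "obesity", diabetes = "diabetes"),
                   function(outc) {
                     aics <- vapply(c(exposures, "ff_intake"), function(ex)
                       fits[[paste0(outc, "~", ex)]]$aic, numeric(1))
                     names(aics) <- c("FF visits/time", "FF visits/food",
                                      "FF intake frequency")
                     akaike_weights(aics)
                   })

  demo <- simulate_tract_demographics(world, world$truth, config)
  changes <- tract_changes(demo$yearA, demo$yearB)
  outliers <- list(method1 = flag_outliers(changes, 1),
                   method2 = flag_outliers(changes, 2))
  stability <- vapply(names(TRACT_DELTA_VARS), function(v)
    stability_quantile(changes, v), numeric(1))
  sens <- list(method1 = refit_without_outliers(analytic, outliers$method1,
                                                exposures),
               method2 = refit_without_outliers(analytic, outliers$method2,
                                                exposures),
               confounder = confounder_check(analytic, exposures))

  manifest <- list(
    package_version = as.character(utils::packageVersion("mobifood")),
    seed = config$seed,
    parameters = list(d_roam_m = 50, min_duration_min = 5, min_events = 2,
                      d_max_m = 200, night_window = c(22, 6),
                      min_users = min_users,
                      tz_offset_hours = config$tz_offset_hours),
    rows = list(pings = nrow(pings), stays = nrow(stays),
                users = length(unique(stays$user_id)),
                neighborhoods_retained = nrow(nm),
                respondents = nrow(respondents),
                analytic = nrow(analytic)),
    exclusions = as.list(excl$counts),
    outlier_tracts = outliers)

  res <- structure(list(world = world, pings = pings, stays = stays,
                        poi = poi, attributed = attributed,
                        user_metrics = um, neighborhood_metrics = nm,
                        respondents = respondents, analytic = analytic,
                        exclusions = excl$counts, table1 = table1,
                        fits = fits, akaike = akaike,
                        tract_changes = changes, outliers = outliers,
                        stability = stability, sensitivity = sens,
                        manifest = manifest, config = config),
                   class = "ff_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_geojson_polygons(world$neighborhoods, p("neighborhoods.geojson"))
    write_geojson_polygons(world$tracts, p("tracts.geojson"))
    write_csv_ts(pings, p("pings.csv"))
    write_csv_ts(stays, p("stays.csv"))
    data.table::fwrite(poi, p("poi.csv"))
    write_csv_ts(attributed, p("attributed_stays.csv"))
    data.table::fwrite(um, p("user_metrics.csv"))
    data.table::fwrite(nm, p("neighborhood_metrics.csv"))
    data.table::fwrite(respondents, p("respondents.csv"))
    data.table::fwrite(analytic, p("analytic_table.csv"))
    data.table::fwrite(table1, p("table1.csv"))
    data.table::fwrite(data.table::rbindlist(lapply(fits, function(f)
      cbind(model = f$model_id, f$terms[, setdiff(names(f$terms), "se")])),
      fill = TRUE), p("model_terms.csv"))
    data.table::fwrite(do.call(rbind, lapply(names(akaike), function(k)
      cbind(outcome = k, as.data.frame(akaike[[k]])))), p("table4.csv"))
    data.table::fwrite(changes, p("tract_changes.csv"))
    writeLines(outliers$method1, p("outliers_m1.txt"))
    writeLines(outliers$method2, p("outliers_m2.txt"))
    data.table::fwrite(rbind(cbind(method = 1, sens$method1),
                             cbind(method = 2, sens$method2)),
                       p("sensitivity_tables.csv"))
    jsonlite::write_json(
      list(neighborhood_ff_propensity =
             as.list(world$truth$neighborhood_ff_propensity),
           intake_coefficients = lapply(world$truth$intake_coefficients,
                                        as.list),
           disease_coefficients = lapply(world$truth$disease_coefficients,
                                         as.list),
           outlier_tracts = world$truth$outlier_tracts),
      p("truth.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(res)
}

#' @export
print.ff_pipeline <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, "):\n", sep = "")
  cat("  pings:", nrow(x$pings), " stays:", nrow(x$stays),
      " users:", length(unique(x$stays$user_id)), "\n")
  cat("  analytic respondents:", nrow(x$analytic), "of",
      nrow(x$respondents), "\n")
  cat("  models fitted:", length(x$fits), "\n")
  invisible(x)
}

#' Validate parameter recovery against the planted truth
#'
#' Compares the fitted exposure odds ratios (from the FF visits/food models,
#' whose measured exposure estimates the planted scaled propensity) to the
#' planted values with CI-coverage checks, and the recovered neighborhood
#' fast food ordering to the planted ordering via Spearman rank correlation.
#'
#' @param results An `ff_pipeline` from [run_pipeline()].
#' @param truth Planted truth to validate against (defaults to the run's
#'   own); supplying a truth from a different world/seed is an error.
#' @param min_rank_cor Required rank correlation between recovered and
#'   planted neighborhood fast food propensities.
#' @return A list of class `recovery_report`: `checks` data.frame
#'   (parameter, planted, estimate, CI, covered), `rank_correlation`, `pass`.
#' @export
validate_recovery <- function(results, truth = results$world$truth,
                              min_rank_cor = 0.9) {
  stopifnot(inherits(results, "ff_pipeline"))
  if (!isTRUE(all.equal(truth$neighborhood_ff_propensity,
                        results$world$truth$neighborhood_ff_propensity)))
    stop("truth does not match the pipeline run (different world or seed)")

  checks <- list()
  tt <- results$fits[["intake~scaled_ff_food"]]$terms
  for (cat in c("infrequent", "moderate", "frequent")) {
    row <- tt[tt$category == cat & tt$term == "scaled_ff_food", ]
    planted <- exp(truth$intake_coefficients$slopes[[cat]])
    checks[[paste0("intake_", cat)]] <- data.frame(
      parameter = paste0("intake_", cat, "_or"), planted = planted,
      estimate = row$or, ci_lo = row$ci_lo, ci_hi = row$ci_hi,
      covered = row$ci_lo <= planted & planted <= row$ci_hi)
  }
  for (outc in c("obesity", "diabetes")) {
    tt <- results$fits[[paste0(outc, "~scaled_ff_food")]]$terms
    row <- tt[tt$term == "scaled_ff_food", ]
    planted <- exp(truth$disease_coefficients[[outc]][["exposure"]])
    checks[[outc]] <- data.frame(
      parameter = paste0(outc, "_or"), planted = planted, estimate = row$or,
      ci_lo = row$ci_lo, ci_hi = row$ci_hi,
      covered = row$ci_lo <= planted & planted <= row$ci_hi)
  }
  checks <- do.call(rbind, checks)
  rownames(checks) <- NULL

  nm <- results$neighborhood_metrics
  planted_prop <- truth$neighborhood_ff_propensity[nm$neighborhood_id]
  rc <- stats::cor(nm$mean_ff_food_pct, planted_prop, method = "spearman")

  structure(list(checks = checks, rank_correlation = rc,
                 pass = all(checks$covered) && rc > min_rank_cor),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  neighborhood FF ordering rank correlation: %.3f\n",
              x$rank_correlation))
  print(x$checks, row.names = FALSE)
  invisible(x)
}
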