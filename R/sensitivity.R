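TRACT_DELTA_VARS <- c(delta_fpl = "pct_above_200fpl",
                      delta_black = "pct_black",
                      delta_hispanic = "pct_hispanic")

#' Year-over-year tract demographic changes
#'
#' Element-wise differences (year B minus year A, percentage points) of the
#' three tract demographic percentages. Tracts missing in either year are
#' excluded and reported via the `"n_unmatched"` attribute; fully disjoint id
#' sets are an error.
#'
#' @param yearA,yearB Tract tables with `tract_id` and the three percentage
#'   columns.
#' @return Data.frame: `tract_id`, `delta_fpl`, `delta_black`,
#'   `delta_hispanic`.
#' @export
tract_changes <- function(yearA, yearB) {
  common <- intersect(yearA$tract_id, yearB$tract_id)
  if (length(common) == 0L) stop("no tract ids in common between the years")
  n_un <- length(union(yearA$tract_id, yearB$tract_id)) - length(common)
  a <- yearA[match(common, yearA$tract_id), ]
  b <- yearB[match(common, yearB$tract_id), ]
  out <- data.frame(tract_id = common)
  for (d in names(TRACT_DELTA_VARS))
    out[[d]] <- b[[TRACT_DELTA_VARS[[d]]]] - a[[TRACT_DELTA_VARS[[d]]]]
  attr(out, "n_unmatched") <- n_un
  out
}

#' Flag outlier tracts by demographic change
#'
#' Method 1 (Tukey): a tract is an outlier for a variable when its change
#' exceeds Q3 + 1.5 IQR or falls below Q1 - 1.5 IQR (quartiles by linear
#' interpolation, `stats::quantile` type 7). Method 2: when the change lies
#' strictly more than two sample standard deviations from the mean. The
#' returned set is the union over the three variables; per-variable sets are
#' attached as the `"per_variable"` attribute.
#'
#' @param changes Output of [tract_changes()].
#' @param method `1` (Tukey fences) or `2` (mean +/- 2 SD).
#' @return Character vector of outlier tract ids.
#' @export
flag_outliers <- function(changes, method = 1) {
  stopifnot(method %in% c(1, 2))
  per_var <- lapply(names(TRACT_DELTA_VARS), function(v) {
    x <- changes[[v]]
    if (method == 1) {
      q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[2] - q[1]
      out <- x > q[2] + 1.5 * iqr | x < q[1] - 1.5 * iqr
    } else {
      out <- abs(x - mean(x)) > 2 * stats::sd(x)
    }
    changes$tract_id[out]
  })
  names(per_var) <- names(TRACT_DELTA_VARS)
  res <- sort(unique(unlist(per_var)))
  attr(res, "per_variable") <- per_var
  res
}

#' Empirical stability threshold
#'
#' The value `z` such that 95% of tracts changed by less than `z` points in
#' absolute value: the empirical 0.95 quantile (linear interpolation) of
#' `|delta|` for one variable.
#'
#' @param changes Output of [tract_changes()].
#' @param variable One of `"delta_fpl"`, `"delta_black"`, `"delta_hispanic"`.
#' @param prob Quantile level.
#' @return Threshold in percentage points.
#' @export
stability_quantile <- function(changes, variable = "delta_fpl", prob = 0.95) {
  x <- changes[[variable]]
  stopifnot(length(x) > 0)
  stats::quantile(abs(x), prob, type = 7, names = FALSE)
}

# the six primary models: each exposure vs intake (unadjusted multinomial)
# and vs obesity/diabetes (adjusted logistic)
fit_primary_models <- function(data,
                               exposures = c("scaled_ff_time",
                                             "scaled_ff_food")) {
  fits <- list()
  for (ex in exposures) {
    fits[[paste0("intake~", ex)]] <- fit_multinomial(data, ex,
                                                     adjusted = FALSE)
    fits[[paste0("obesity~", ex)]] <- fit_binary(data, "obesity", ex)
    fits[[paste0("diabetes~", ex)]] <- fit_binary(data, "diabetes", ex)
  }
  fits
}

exposure_terms <- function(fit) {
  tt <- fit$terms[fit$terms$term == fit$exposure, , drop = FALSE]
  key <- if ("category" %in% names(tt)) paste(fit$model_id, tt$category)
         else fit$model_id
  data.frame(model = fit$model_id, outcome = fit$outcome,
             exposure = fit$exposure,
             category = if ("category" %in% names(tt)) tt$category else NA,
             key = key, or = tt$or, stringsAsFactors = FALSE)
}

#' Refit the primary models without outlier tracts
#'
#' Drops respondents living in the outlier tracts, refits the six primary
#' models (two exposures against intake, obesity, and diabetes), and reports
#' the percentage change of each exposure odds ratio relative to the
#' full-sample fit. Changes above 10% are flagged as meaningful. Models whose
#' outcome loses a category after removal are skipped with a flag.
#'
#' @param analytic Analytic respondent table with `tract_id` and linked
#'   contextual variables.
#' @param outlier_tracts Character vector of tract ids to remove.
#' @param exposures Contextual exposure columns.
#' @return Data.frame: `model`, `outcome`, `exposure`, `category`,
#'   `or_full`, `or_reduced`, `pct_change`, `flagged`.
#' @export
refit_without_outliers <- function(analytic, outlier_tracts,
                                   exposures = c("scaled_ff_time",
                                                 "scaled_ff_food")) {
  reduced <- analytic[!(analytic$tract_id %in% outlier_tracts), , drop = FALSE]
  full_fits <- fit_primary_models(analytic, exposures)
  rows <- lapply(names(full_fits), function(id) {
    fx <- exposure_terms(full_fits[[id]])
    red <- tryCatch({
      f <- full_fits[[id]]
      if (f$outcome == "ff_intake")
        fit_multinomial(reduced, f$exposure, adjusted = f$adjusted)
      else fit_binary(reduced, f$outcome, f$exposure, adjusted = f$adjusted)
    }, error = function(e) NULL)
    if (is.null(red)) {
      fx$or_reduced <- NA_real_
      fx$pct_change <- NA_real_
      fx$flagged <- NA
    } else {
      rx <- exposure_terms(red)
      fx$or_reduced <- rx$or[match(fx$key, rx$key)]
      fx$pct_change <- 100 * (fx$or_reduced - fx$or) / fx$or
      fx$flagged <- abs(fx$pct_change) > 10
    }
    names(fx)[names(fx) == "or"] <- "or_full"
    fx$key <- NULL
    fx
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' General-mobility confounder check
#'
#' Refits the adjusted obesity and diabetes models for each fast food
#' exposure with trips/day added as a covariate and reports the percentage
#' change of the exposure adjusted odds ratio; changes above 10% would
#' indicate meaningful confounding by general mobility.
#'
#' @param analytic Analytic respondent table with `scaled_trips_day` linked.
#' @param exposures Contextual exposure columns.
#' @return Data.frame: `outcome`, `exposure`, `aor_base`, `aor_with_trips`,
#'   `pct_change`, `flagged`.
#' @export
confounder_check <- function(analytic,
                             exposures = c("scaled_ff_time",
                                           "scaled_ff_food")) {
  rows <- list()
  for (outc in c("obesity", "diabetes")) {
    for (ex in exposures) {
      base <- fit_binary(analytic, outc, ex)
      with_td <- fit_binary(analytic, outc, ex,
                            covariates = c(ADJUSTMENT_COVARIATES,
                                           "scaled_trips_day"))
      b <- base$terms$or[base$terms$term == ex]
      w <- with_td$terms$or[with_td$terms$term == ex]
      rows[[paste(outc, ex)]] <- data.frame(
        outcome = outc, exposure = ex, aor_base = b, aor_with_trips = w,
        pct_change = 100 * (w - b) / b,
        flagged = abs(100 * (w - b) / b) > 10)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
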