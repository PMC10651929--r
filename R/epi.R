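STUDY_VARIABLES <- c("age_group", "gender", "race_ethnicity", "education",
                     "income", "ff_intake", "obesity", "diabetes")
ADJUSTMENT_COVARIATES <- c("age_group", "gender", "race_ethnicity",
                           "education", "income")

#' Apply the analytic-sample exclusion rules
#'
#' Removes respondents sequentially: (1) missing residential information,
#' (2) residence in a rural area, (3) missing data on any study variable.
#' A record removed by an earlier rule is not recounted by a later one.
#'
#' @param respondents Full respondent table.
#' @param study_vars Variables whose missingness triggers rule 3.
#' @return List with `analytic` (data.frame) and `counts` (named integer
#'   vector of per-rule removals).
#' @export
apply_exclusions <- function(respondents, study_vars = STUDY_VARIABLES) {
  n0 <- nrow(respondents)
  # blank strings count as missing so CSV round-trips behave like in-memory NA
  blank <- function(x) is.na(x) | (is.character(x) & !nzchar(as.character(x)))
  keep <- !(blank(respondents$neighborhood_id) | blank(respondents$tract_id))
  n_res <- sum(!keep)
  d <- respondents[keep, , drop = FALSE]

  rural <- !is.na(d$rural) & d$rural
  n_rural <- sum(rural)
  d <- d[!rural, , drop = FALSE]

  sv <- d[, intersect(study_vars, names(d)), drop = FALSE]
  miss <- if (ncol(sv) == 0L) rep(FALSE, nrow(d)) else
    Reduce(`|`, lapply(sv, blank))
  n_miss <- sum(miss)
  d <- d[!miss, , drop = FALSE]

  list(analytic = d,
       counts = c(missing_residence = n_res, rural = n_rural,
                  missing_variable = n_miss, analytic_n = n0 - n_res -
                    n_rural - n_miss))
}

#' Compare full and analytic samples
#'
#' For each categorical study variable, tabulates counts and column
#' percentages over non-missing values in the full and analytic samples, and
#' computes the Pearson chi-square p-value of the sample-by-category
#' contingency table. Variables with fewer than two non-empty categories get
#' an `NA` p-value.
#'
#' @param full,analytic Respondent tables sharing code lists.
#' @param variables Variables to compare.
#' @return Data.frame: `variable`, `category`, `n_full`, `pct_full`,
#'   `n_analytic`, `pct_analytic`, `p_value`.
#' @export
compare_samples <- function(full, analytic, variables = STUDY_VARIABLES) {
  rows <- lapply(variables, function(v) {
    xf <- full[[v]][!is.na(full[[v]])]
    xa <- analytic[[v]][!is.na(analytic[[v]])]
    lev <- sort(unique(c(as.character(xf), as.character(xa))))
    if (is.factor(full[[v]])) lev <- levels(full[[v]])
    tf <- table(factor(as.character(xf), levels = lev))
    ta <- table(factor(as.character(xa), levels = lev))
    nonempty <- tf + ta > 0
    p <- if (sum(nonempty) < 2) NA_real_ else
      suppressWarnings(stats::chisq.test(rbind(tf[nonempty],
                                               ta[nonempty]))$p.value)
    data.frame(variable = v, category = lev,
               n_full = as.integer(tf), pct_full = 100 * as.numeric(tf) /
                 max(sum(tf), 1),
               n_analytic = as.integer(ta),
               pct_analytic = 100 * as.numeric(ta) / max(sum(ta), 1),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# shared post-fit checks and Wald machinery -----------------------------------

wald_terms <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(estimate = est, se = se, or = exp(est),
             ci_lo = exp(est - z * se), ci_hi = exp(est + z * se),
             p = 2 * stats::pnorm(-abs(est / se)))
}

check_estimable <- function(data, exposure) {
  x <- data[[exposure]]
  if (is.null(x)) stop("exposure '", exposure, "' not found")
  ux <- unique(x[!is.na(x)])
  if (length(ux) < 2)
    stop("exposure '", exposure, "' is constant: coefficient inestimable")
}

new_ff_fit <- function(model_id, outcome, exposure, adjusted, terms, fit, n) {
  ll <- as.numeric(stats::logLik(fit))
  k <- attr(stats::logLik(fit), "df")
  structure(list(model_id = model_id, outcome = outcome, exposure = exposure,
                 adjusted = adjusted, terms = terms,
                 aic = stats::AIC(fit), loglik = ll, k = k, n = n, fit = fit),
            class = "ff_fit")
}

#' @export
print.ff_fit <- function(x, ...) {
  cat(sprintf("%s model of %s on %s (%s), n = %d, AIC = %.1f\n",
              if (x$outcome == "ff_intake") "Multinomial logistic"
              else "Binary logistic",
              x$outcome, x$exposure,
              if (x$adjusted) "adjusted" else "unadjusted", x$n, x$aic))
  tt <- x$terms
  tt$or <- sprintf("%.2f (%.2f-%.2f)", tt$or, tt$ci_lo, tt$ci_hi)
  print(tt[, intersect(c("category", "term", "or", "p"), names(tt))],
        row.names = FALSE)
  invisible(x)
}

#' Fit the multinomial intake model
#'
#' Maximum-likelihood multinomial logistic regression of four-level fast food
#' intake (reference "never") on a neighborhood contextual exposure,
#' optionally adjusted for the sociodemographic covariates. Reports per
#' outcome category the odds ratio per scaled-exposure unit with Wald 95% CI.
#'
#' @param data Analytic respondent table with linked contextual variables.
#' @param exposure Name of the exposure column (e.g. `"scaled_ff_time"`).
#' @param adjusted Add the sociodemographic covariates?
#' @param covariates Covariate names used when `adjusted = TRUE`.
#' @return An object of class `ff_fit`.
#' @export
fit_multinomial <- function(data, exposure, adjusted = FALSE,
                            covariates = ADJUSTMENT_COVARIATES) {
  check_estimable(data, exposure)
  data$ff_intake <- droplevels(factor(data$ff_intake,
                                      levels = c("never", "infrequent",
                                                 "moderate", "frequent")))
  if (nlevels(data$ff_intake) < 2) stop("ff_intake has a single level")
  rhs <- if (adjusted) paste(c(exposure, covariates), collapse = " + ")
         else exposure
  fml <- stats::as.formula(paste("ff_intake ~", rhs))
  fit <- nnet::multinom(fml, data = data, trace = FALSE, maxit = 500,
                        reltol = 1e-8, Hess = TRUE)
  if (!is.null(fit$convergence) && fit$convergence != 0)
    stop("multinomial fit did not converge (convergence code ",
         fit$convergence, ")")
  cf <- stats::coef(fit)
  se <- summary(fit)$standard.errors
  if (is.null(dim(cf))) {  # two outcome levels: nnet returns plain vectors
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(levels(data$ff_intake)[2], names(cf)))
    se <- matrix(se, nrow = 1, dimnames = dimnames(cf))
  }
  if (any(!is.finite(cf)) || any(abs(cf) > 15))
    stop("multinomial fit unstable (possible separation); |coef| > 15")
  terms <- do.call(rbind, lapply(rownames(cf), function(cat) {
    keep <- colnames(cf) != "(Intercept)"
    cbind(data.frame(category = cat, term = colnames(cf)[keep]),
          wald_terms(cf[cat, keep], se[cat, keep]))
  }))
  rownames(terms) <- NULL
  new_ff_fit(paste0("intake~", exposure, if (adjusted) "+cov" else ""),
             "ff_intake", exposure, adjusted, terms, fit, nrow(data))
}

#' Fit a binary disease model
#'
#' Logistic regression of obesity or diabetes on a contextual exposure or on
#' the categorical self-reported intake, adjusted for the sociodemographic
#' covariates.
#'
#' @param data Analytic respondent table.
#' @param outcome `"obesity"` or `"diabetes"`.
#' @param exposure Exposure column name (numeric contextual variable, or
#'   `"ff_intake"` for the categorical self-report).
#' @param adjusted Add the sociodemographic covariates?
#' @param covariates Covariate names; extra covariates (e.g.
#'   `"scaled_trips_day"`) may be appended by sensitivity analyses.
#' @return An object of class `ff_fit`.
#' @export
fit_binary <- function(data, outcome, exposure, adjusted = TRUE,
                       covariates = ADJUSTMENT_COVARIATES) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome '", outcome, "' has a single observed level")
  if (exposure != "ff_intake") check_estimable(data, exposure)
  if ("ff_intake" %in% c(exposure, if (adjusted) covariates))
    data$ff_intake <- factor(data$ff_intake,
                             levels = c("never", "infrequent", "moderate",
                                        "frequent"))
  rhs <- if (adjusted) paste(c(exposure, covariates), collapse = " + ")
         else exposure
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::glm(fml, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 500))
  if (!fit$converged) stop("logistic fit did not converge")
  cf <- stats::coef(fit)
  if (any(!is.finite(cf)) || any(abs(cf) > 15))
    stop("logistic fit unstable (possible separation); |coef| > 15")
  se <- sqrt(diag(stats::vcov(fit)))
  keep <- names(cf) != "(Intercept)"
  terms <- cbind(data.frame(term = names(cf)[keep]),
                 wald_terms(cf[keep], se[keep]))
  rownames(terms) <- NULL
  new_ff_fit(paste0(outcome, "~", exposure, if (adjusted) "+cov" else ""),
             outcome, exposure, adjusted, terms, fit, nrow(data))
}

#' Akaike weights for non-nested model comparison
#'
#' For candidate models with AIC values \eqn{A_i}, computes
#' \eqn{\Delta_i = A_i - \min_k A_k} and weights
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_k \exp(-\Delta_k/2)} (numerically
#' stable via the min subtraction). A model's weight is interpreted as the
#' probability that it is the best model in the candidate set.
#'
#' @param aic Numeric vector of AIC values (optionally named), length >= 2.
#' @return Object of class `akaike_comparison`: data.frame with `model`,
#'   `aic`, `delta`, `weight`.
#' @export
akaike_weights <- function(aic) {
  if (length(aic) == 0L) stop("no AIC values supplied")
  if (length(aic) < 2L || any(!is.finite(aic)))
    stop("need at least two finite AIC values")
  delta <- aic - min(aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  structure(data.frame(model = if (is.null(names(aic)))
                         paste0("model", seq_along(aic)) else names(aic),
                       aic = unname(aic), delta = unname(delta),
                       weight = unname(w)),
            class = c("akaike_comparison", "data.frame"))
}
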