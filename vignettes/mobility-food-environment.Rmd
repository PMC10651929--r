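---
title: "From smartphone pings to neighborhood fast food exposure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From smartphone pings to neighborhood fast food exposure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mobifood implements a complete analysis chain linking passively collected
smartphone geolocation data to diet and diet-related disease at the
neighborhood level. This vignette documents the methods: the stay-detection
and attribution algorithms, the exposure metrics, the regression and
model-comparison machinery, the sensitivity analyses, and the synthetic world
that stands in for the restricted real data sources.

## The analysis chain

1. **Stay detection.** Each user's time-ordered GPS pings are clustered into
   *stays* (dwell events). A greedy sequential rule grows the current cluster
   with the next ping iff, after inclusion, the maximum haversine distance
   from any member ping to the cluster's coordinate-wise *median* centroid is
   strictly below a roaming distance `d_roam_m` (default 50 m). On violation
   the cluster closes — emitted as a stay when it has at least `min_events`
   pings (default 2) and spans at least `min_duration_min` minutes (default
   5) — and the violating ping opens the next cluster. The first and last
   member pings mark the stay's start and end. The median centroid makes the
   rule robust to heavy-tailed GPS error; the strict inequality makes
   boundary behavior reproducible.
2. **POI attribution.** Each stay is attributed to the haversine-nearest
   point of interest, but only when that distance is strictly below
   `d_max_m` (default 200 m); ties resolve to the smallest `poi_id`. Food
   outlets are identified by category; fast food (FF) outlets are food
   outlets whose name matches a validated chain-brand list under token-prefix
   matching (case-folded, punctuation stripped), so "McDonald's #1234"
   matches the brand "McDonald's" while "Subwayside Deli" does not match
   "Subway".
3. **Per-user metrics.** The day is partitioned into three half-open local
   periods — [00:00, 11:00), [11:00, 16:00), [16:00, 24:00) — and a
   (date, period) block is *observed* when at least one stay starts in it.
   *FF visits/time* is the percentage of a user's observed periods containing
   at least one FF-attributed stay; *FF visits/food* is the percentage of the
   user's food-outlet visits that were FF; *trips/day* is the number of
   trajectories between consecutive stays divided by the number of
   observation days (local dates with at least one stay). The home
   neighborhood is the one holding the majority of the user's stay duration
   overlapping the 22:00–06:00 window, by point-in-polygon on stay centroids.
4. **Aggregation and linkage.** User metrics are averaged (arithmetic mean,
   population variance) over users homed in each neighborhood; percentage
   variables are divided by 10 so one scaled unit equals a 10-point increase.
   Neighborhoods with fewer than `min_users` residents (default 5, an
   aggregate-only reporting floor) are dropped. The scaled contextual
   variables are attached to survey respondents by residential neighborhood.
5. **Models.** After sequential exclusions (missing residence, rural
   residence, missing study variables), intake is modelled with multinomial
   logistic regression (reference "never"; unadjusted and adjusted), and
   obesity/diabetes with binary logistic regression, all with Wald 95%
   intervals. Non-nested models of the same outcome are compared with Akaike
   weights \(w_i = e^{-\Delta_i/2} / \sum_k e^{-\Delta_k/2}\),
   \(\Delta_i = \mathrm{AIC}_i - \min_k \mathrm{AIC}_k\).
6. **Sensitivity.** Year-over-year tract demographic changes (share of the
   population above 200% of the FPL, share Black, share Hispanic) are
   screened for outlier tracts by Tukey fences (method 1) and by two sample
   standard deviations from the mean (method 2); the union over the three
   variables is removed and the six primary models refit, flagging odds-ratio
   changes above 10%. A separate check refits the disease models with
   trips/day added as a covariate. Stability is summarized by the empirical
   0.95 quantile of the absolute changes.

## Distances, time, and geometry

All distances are haversine on WGS84 with Earth radius 6,371,000 m, in both
the generator and the pipeline, so the two always agree on geometry. POIs are
represented as points (their centroids). Timestamps are stored in UTC;
"local" time is UTC plus one fixed configurable offset (default −8 h), with
no daylight-saving transitions — period and night-window boundaries are
interpreted in that local clock. Point-in-polygon tests use `mgcv::in.out`.

## Numerical choices

- Quartiles and quantiles use linear interpolation (`stats::quantile`
  type 7); Tukey fences therefore follow that convention, and the stability
  quantile of |Δ| = 1…100 is 95.05, not 95.
- Method-2 outliers use the *sample* standard deviation and a strict
  inequality, so a constant change vector produces no outliers under either
  method.
- The multinomial fit (via `nnet::multinom`) uses a log-likelihood
  convergence tolerance of 1e-8 and at most 500 iterations; the binary fits
  (`stats::glm`) use the same limits. Non-convergence, rank deficiency, or
  coefficients beyond ±15 on the log-odds scale (a separation symptom) raise
  errors rather than returning unstable estimates.
- AIC counts every estimated coefficient, including the per-category
  intercepts of the multinomial model; Akaike weights subtract the minimum
  AIC before exponentiating, so arbitrarily spread AIC values remain finite.
- Attribution ties at identical distance resolve to the smallest `poi_id`;
  clustering ties at exactly `d_roam_m` close the cluster (strict "<").
- A cluster failing the event-count or duration floor is discarded whole;
  its pings are not reassigned to neighbors.

## Design decisions where the design was open

- **Observed periods and observation days are stay-based**, not ping-based:
  trip counts, observation days, and period denominators then share one event
  basis. A stay belongs to the period of its *start* time; multi-period
  stays are not split (one visit, one period).
- **Trips/day is left unscaled** by default. Dividing by 10 is exact for
  percentage variables (0–100 maps onto 0–10) but has no analogue for a rate
  that already lives within 0–10 in practice; a min–max alternative is
  available via `rescale_metrics(trips_mode = "minmax")`. Because the scaling
  is linear, applying it before or after averaging is equivalent.
- **Fits are unweighted**: no survey design weights enter the regressions.
- **Covariates use treatment coding** with the first listed category of each
  code list as reference.
- **No maximum time gap** is imposed within a stay: two pings hours apart at
  the same spot form one stay. Day-to-day behavior in the generator is
  exchangeable; no behavioral autocorrelation is modelled.
- **Tukey fences are computed on signed changes**, per variable, not on
  absolute changes.

## The synthetic world

Real mobility feeds, health-survey microdata, and commercial POI databases
are access-restricted, so the package generates a synthetic study region with
planted ground truth; every downstream stage is validated against that truth.

- **Geometry.** Neighborhoods are grid cells (default 12 cells of 2 km) at
  an urban mid-latitude anchor, each split into tract strips (default 4).
  POIs scatter uniformly inside cells; half sell food, and a per-neighborhood
  fraction of food POIs (drawn from `ff_fraction_range`) are FF outlets named
  after real chain brands so the classifier can recover them.
- **Behavior.** Each user has a home anchor (balanced across neighborhoods),
  usually a workplace, and food-outlet visit opportunities in the morning,
  lunch, and dinner slots. The probability that a food visit is to an FF
  outlet is the home neighborhood's planted propensity (neighborhoods are
  linearly spaced across `ff_propensity_range`, default 0.05–0.35), which is
  exactly the quantity FF visits/food estimates. Home and work anchors are
  kept at least 260 m from every POI — a zoning-style separation — so
  residential dwells are not spuriously attributed to outlets.
- **Measurement.** Pings are emitted within each stay at a 5–15 min cadence
  and jittered with isotropic Gaussian noise whose scale is set so the
  *median* radial error equals the configured accuracy (21 m by default;
  for a Rayleigh radius the median is \(\sigma\sqrt{2\ln 2}\)). Whole
  (day, period) blocks are dropped with probability `period_dropout_prob`
  to emulate phones going out of service.
- **Survey.** Respondents draw demographics from urban survey margins, a
  residential tract, intake from a multinomial logit on the scaled true
  neighborhood exposure (planted ORs 1.13/1.26/1.35 per scaled unit), and
  obesity/diabetes from logistic models (planted ORs 1.16 and 1.15, plus
  modest age-65+ and low-income effects so that adjustment is exercised; the
  intake model plants no demographic effects, making its unadjusted fit
  consistent). Missing residence, rural residence, and missing study
  variables are planted at configurable rates to drive the exclusion rules.
- **Tract demographics.** Two yearly tables of the three percentages;
  non-outlier tracts move by centered Gaussian noise whose default SDs
  (16/1.96, 10/1.96, 15/1.96 points) place the 95% absolute-change quantile
  at 16, 10, and 15 points; planted outlier tracts shift by 30 points and
  should be flagged by both outlier methods.

What the generator does **not** emulate: road-network trajectories,
device-OS heterogeneity, within-user day-to-day autocorrelation, seasonal or
weekday/weekend structure, within-neighborhood heterogeneity of FF
propensity, and address geocoding (respondents carry tract ids directly).
Passing tests therefore demonstrate algorithmic correctness and statistical
calibration under these stylized conditions, not robustness to every
real-data pathology.

## Validation design and problem sizes

The test suite checks each geometric primitive against an independent
brute-force oracle (greedy clustering re-derived in plain R over 200 random
50-ping streams; all-pairs nearest-neighbor attribution over random
stay/POI sets), and the statistical stack by parameter recovery: across 200
simulated surveys of 5,000 respondents, the planted frequent-intake OR of
1.35 and obesity OR of 1.16 must be recovered with 95% CI coverage between
0.92 and 0.98 and absolute mean log-OR bias below 0.02, and a planted null
effect must be rejected at the two-sided 5% level at its nominal rate. The
outlier-removal refit property uses a survey of 40,000 respondents so that
the sampling noise induced by removing a few percent of respondents sits
well below the 10% confounding criterion (and the 2% stability observed for
homogeneous effects); smaller surveys would confound sampling noise with the
property under test. The end-to-end pipeline tests run a 12-neighborhood,
360-user, 10-day world, large enough that the recovered neighborhood FF
ordering is stable (rank correlation above 0.9).

## Known limitations

- Neighborhood exposure is measured with sampling error (finitely many users
  per neighborhood), which attenuates contextual effect estimates slightly;
  at the default panel sizes the attenuation is well under the CI width.
- The analysis is ecological by construction: area-level exposures are
  linked to individual outcomes, and the models carry the usual caveats of
  contextual inference.
- `compare_samples` applies the chi-square test to full-vs-analytic tables
  even though the analytic sample is a subset of the full sample; the
  p-values are descriptive, mirroring standard survey reporting practice.
- The CLI (`inst/cli/mobifood.R`) is a thin wrapper; the package functions
  are the primary interface.
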