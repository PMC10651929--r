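# mobifood

Large-scale smartphone mobility data — billions of timestamped GPS "pings" —
makes it possible to observe where people actually go, including which food
outlets they visit, continuously and without recall bias. mobifood is an R
package for epidemiologists and food-environment researchers that turns raw
ping streams into neighborhood-level fast food (FF) exposure measures and
tests whether those measures predict individual diet and diet-related disease
reported in a population health survey.

The package implements the full chain:

- **Stay detection** — greedy sequential clustering of each user's pings: a
  ping joins the current cluster iff, after inclusion, the maximum haversine
  distance from any member to the coordinate-wise *median* centroid stays
  below a roaming distance *d*<sup>roam</sup> = 50 m; stays need ≥ 2 pings
  and ≥ 5 min.
- **POI attribution** — each stay maps to its nearest point of interest
  within *d*<sup>max</sup> = 200 m; food outlets come from the category
  taxonomy and FF outlets from a validated chain-brand list with normalized
  token-prefix name matching.
- **Exposure metrics** — per user: *FF visits/time* (percentage of observed
  daily periods — before 11:00, 11:00–16:00, after 16:00 — with an FF
  visit), *FF visits/food* (percentage of food-outlet visits that were FF),
  *trips/day*, and a home neighborhood inferred from 22:00–06:00 activity.
- **Aggregation and linkage** — user metrics averaged within neighborhoods,
  rescaled so one unit = 10 percentage points, and linked as contextual
  variables to survey respondents by residence.
- **Models** — multinomial logistic regression of four-level FF intake
  (reference "never") and binary logistic regression of obesity and diabetes,
  unadjusted and adjusted for sociodemographics, with Wald 95% CIs; the
  non-nested models are compared by Akaike weights
  *w<sub>i</sub>* = exp(−Δ<sub>i</sub>/2) / Σ<sub>k</sub> exp(−Δ<sub>k</sub>/2),
  Δ<sub>i</sub> = AIC<sub>i</sub> − min AIC.
- **Sensitivity analyses** — tract-level demographic stability between two
  years, outlier-tract detection by Tukey fences and by mean ± 2 SD, refits
  after removing respondents in outlier tracts (flagging odds-ratio changes
  > 10%), and a trips/day confounder check.

Because real mobility feeds, survey microdata, and commercial POI databases
are access-restricted, the package ships a **synthetic world generator** with
planted ground truth (per-neighborhood FF propensities, intake and disease
coefficients, demographic outlier tracts), so every stage is testable and the
whole pipeline validates by parameter recovery. See the methods vignette
(`vignettes/mobility-food-environment.Rmd`) for the algorithms, defaults, and
design decisions.

## Worked example

```r
library(mobifood)
res <- run_pipeline(world_config(seed = 1))
res
#> Pipeline run (seed 1):
#>   pings: 1362948  stays: 98893  users: 600
#>   analytic respondents: 1357 of 2000
#>   models fitted: 10
```

A synthetic 12-neighborhood world with 600 users observed for 28 days yields
~1.36 M pings and ~99 k stays; after exclusions, 1,357 of 2,000 survey
respondents form the analytic sample. The fitted obesity model recovers the
planted exposure effect (true OR 1.16 per scaled unit):

```r
res$fits[["obesity~scaled_ff_food"]]
#> Binary logistic model of obesity on scaled_ff_food (adjusted), n = 1357, AIC = 1626.1
#>            term               or          p
#>  scaled_ff_food 1.17 (1.03-1.34) 0.01938177
#>  ...
```

Akaike weights compare the three diabetes models (the two mobility exposures
vs self-reported intake); here the mobility variables carry almost all the
weight:

```r
res$akaike$diabetes
#>                 model      aic     delta     weight
#> 1      FF visits/time 1046.944 0.6217005 0.39547704
#> 2      FF visits/food 1046.323 0.0000000 0.53966199
#> 3 FF intake frequency 1050.560 4.2373942 0.06486096
```

`validate_recovery()` checks every planted parameter against its fitted CI
and the recovered neighborhood FF ordering:

```r
validate_recovery(res)
#> Parameter recovery PASS
#>   neighborhood FF ordering rank correlation: 0.986
#>             parameter planted estimate     ci_lo    ci_hi covered
#>  intake_infrequent_or    1.13 1.194261 0.9776788 1.458822    TRUE
#>    intake_moderate_or    1.26 1.238101 1.0269359 1.492688    TRUE
#>    intake_frequent_or    1.35 1.422937 1.1968339 1.691756    TRUE
#>            obesity_or    1.16 1.170861 1.0258394 1.336385    TRUE
#>           diabetes_or    1.15 1.199000 1.0029159 1.433421    TRUE
```

`run_pipeline(config, out_dir = "...")` additionally writes every stage's
table (pings, stays, attributed stays, user and neighborhood metrics, the
analytic table, model terms, Akaike comparison, tract changes, outlier lists,
sensitivity tables) plus `truth.json` and a run manifest. A thin CLI over the
same functions lives at `inst/cli/mobifood.R`.

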