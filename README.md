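# pyroloss

Self-comparison matched case-control analysis of gestational exposure to
fire-sourced fine particulate matter (PM2.5) and pregnancy loss.

## The problem

Open fires — wildfires, forest and agricultural burning — episodically load
the air with fine particles that are chemically richer in toxic organics
than typical urban PM2.5. Epidemiological interest centres on whether the
fire-sourced fraction of PM2.5 carries a larger per-microgram risk of
pregnancy loss (miscarriage or stillbirth) than PM2.5 from other sources,
and how much of the PM2.5-linked loss burden it explains. The design of
choice in retrospective survey data is the *self-comparison* matched
case-control study: each mother's lost pregnancy is compared against her own
successful deliveries, cancelling everything constant about her, with
exposure averaged over gestational windows of matched length.

`pyroloss` is for biostatisticians and environmental epidemiologists who
want that full analysis chain as tested, reusable R functions — including a
synthetic-data generator with the statistical structure the design assumes,
so every stage can be validated by parameter recovery without access to
survey microdata or chemical-transport-model runs.

## The model

Exposure assessment combines paired simulations (with and without fire
emissions) with an annual satellite reference on a 0.1-degree grid:

    rho_m,y = (PM_wfire - PM_nofire) / PM_wfire          (fire fraction, clamped to [0,1])
    eta_y   = PM_satellite,y / mean_m(PM_wfire,m,y)      (annual calibration)
    total   = eta * PM_wfire;  fire = rho * total;  nonfire = (1 - rho) * total

Inference is conditional logistic regression on mother-matched sets (one
case, m controls), maximising the exact conditional likelihood

    l(beta) = sum_s [ x_case(s) beta - log sum_{j in s} exp(x_j beta) ]

by Newton-Raphson with step-halving, adjusted for maternal-age band, natural
splines of window-mean temperature (df 3), humidity (df 3) and conception
month (df 4), calendar-year indicators, and mutual adjustment of fire by
non-fire PM2.5. Impact is summarised by attributable fractions,

    AF = 1 - 1 / exp[beta (mean exposure - TMREL)]

with TMREL 0 ug/m3 for fire and 10 ug/m3 for non-fire PM2.5.

## Worked example

Simulate a small world, build the matched cohort, and fit the fully
adjusted, mutually adjusted model:

```r
library(pyroloss)

cfg    <- world_config(n_mothers = 4000, rng_seed = 2026)
fields <- simulate_fields(cfg)
events <- simulate_mothers(cfg, fields, return_series = TRUE)
series <- attr(events, "exposure_series")
cohort <- build_cohort(events, series)
cohort
#> Matched cohort: 1720 sets, 5987 events (1720 cases, 4267 controls)
#>   eligible sets per subset:
#>     miscarriage            1104
#>     stillbirth             616
#>     ...

fit <- fit_clogit(cohort, c(list(term_linear("fire"), term_linear("nonfire")),
                            adjustment_terms()))
fit
#> Conditional logistic fit: 1720 sets, 5987 events, logLik -1956.40 (4 iterations)
#>   odds ratios per unit increment:
#>     fire         OR 1.0525 (95% CI 0.9827, 1.1273) per 1
#>     nonfire      OR 1.0221 (95% CI 1.0011, 1.0436) per 1
```

The world was generated with true ORs of 1.051 (fire) and 1.014 (non-fire)
per 1 ug/m3; at 1,720 sets both are recovered within their confidence
intervals (at ~20,000 sets the intervals tighten around the truth — that
run is the first acceptance target). Attributable fractions from the same
fit and cohort:

```r
imp <- impact_summary(fit, cohort)
imp[imp$stratum == "overall", c("source", "or", "mean_exposure", "tmrel", "af", "share")]
#>    source   or mean_exposure tmrel     af share
#> 1    fire 1.05          1.41     0 0.0696 0.103
#> 2 nonfire 1.02         52.83    10 0.6086 0.897
```

so fire PM2.5, about 2.6% of the cohort's mean PM2.5 concentration here,
accounts for about 10% of the PM2.5-linked loss burden in this small
simulation. Sensitivity subsets (`subset_cohort(cohort, "bidirectional")`,
`"transported_fire"`, `"recall_5"`, ...), subgroup interactions
(`fit_subgroup_interaction`), nonlinear exposure-response
(`fit_nonlinear_exposure`), and a one-call orchestration (`run_pipeline`,
with a YAML config and a thin CLI at `inst/scripts/pyroloss.R`) are
documented in the package help and the methods vignette
(`vignettes/pyroloss-methods.Rmd`).

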