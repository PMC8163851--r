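---
title: "Methods: matched analysis of fire-sourced PM2.5 and pregnancy loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched analysis of fire-sourced PM2.5 and pregnancy loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroloss)
```

## The design

Pregnancy loss (miscarriage, gestation under 5 months, or stillbirth, 5
months and longer) is compared within mothers: each retained mother
contributes one matched set consisting of her most recent in-period loss
(the case) and all of her live births with valid exposure (the controls).
Because comparisons are within a mother, everything constant about her —
genetics, persistent socioeconomic circumstances, stable local conditions —
cancels from the analysis. What remains identifiable is the contrast in
gestational exposure between the lost pregnancy and the successful ones.

Exposure windows are matched, not gestations: the case is averaged from its
conception month to its termination month, and every control is averaged
over a window of the *case's* gestation length starting at the control's own
conception month. This prevents the window length itself (losses gestate
1-9 months, live births 9) from confounding the exposure contrast. An event
whose window is not fully covered by the exposure series is
exposure-invalid; a set whose case is invalid, or with no valid control, is
dropped.

Dates are integer century-month codes (months since January 1900), so all
window arithmetic is exact.

## Exposure model

Two paired simulation fields — PM2.5 with and without open-fire emissions —
are combined with an annual satellite-style reference:

- monthly fire fraction: `rho = (wfire - nofire) / wfire`, clamped into
  [0, 1]. Simulated chemistry is nonlinear, so the without-fire run can
  exceed the with-fire run; a negative fire concentration is
  uninterpretable, and clamping events are counted and reported.
- annual calibration rate: `eta_y = satellite_y / mean(monthly wfire)`,
  constant within a calendar year, requiring complete years.
- decomposition: total `= eta * wfire`; fire `= rho * total`; non-fire
  `= (1 - rho) * total`. Fire plus non-fire equals total identically, and
  the calibrated annual mean reproduces the reference raster exactly — both
  identities are asserted in the test suite.

The coarse fields (`pm_wfire`, `pm_nofire`, `rho`, temperature, humidity)
are downscaled to the 0.1-degree satellite grid before calibration, by
inverse-squared-distance weighting of the 4 nearest coarse cell centers
under great-circle distance (an exact hit returns the coarse value; the
interpolation is a convex combination, so field bounds are preserved).
Neither the neighbour count, the power, nor the metric is canonical; k = 4
with power 2 is the common default for this kind of product, and the choice
is recorded here rather than inferred from anything. Burned-area fraction
and dry-matter emission are pixel products: they are assigned from the
containing cell without interpolation. Point locations map to fine cells by
half-open containment with the lower edge inclusive.

## The conditional likelihood

With exactly one case per set the conditional likelihood is exact and free
of tie-handling variants. For set \(s\) with member covariates \(x_j\),

\[ \ell(\beta) = \sum_s \Big[ x_{case(s)}\beta - \log \sum_{j \in s}
   e^{x_j \beta} \Big]. \]

The fitter is Newton-Raphson on this function: score
\(\sum_s (x_{case} - \bar x_s)\) and observed information
\(\sum_s \sum_j w_j (x_j-\bar x_s)(x_j-\bar x_s)'\) with within-set softmax
weights \(w_j\). Steps that fail to increase the log-likelihood are halved
(up to 10 times); convergence is a relative change below 1e-10 within 50
iterations, and a step that cannot improve beyond rounding noise is treated
as converged. Covariates without within-set variation (or collinear after
within-set centering, detected by pivoted QR) are cancelled by the
conditioning; they are reported as `NA` with a flag, and the other
estimates equal those of the model omitting them — the design's core
identification property, asserted as a test. The covariance is the inverse
observed information; odds ratios carry Wald 95% intervals per stated unit
increments (1 ug/m3 PM2.5, 1% burned area, 10 g/m3/month dry matter).

The adjustment set mirrors the full specification: maternal-age band
(<20, 20-24, 25-29, 30-34, 35-39, >=40; lowest band is the reference),
natural cubic splines for window-mean temperature (df 3), humidity (df 3)
and conception month (df 4), and calendar-year-of-conception indicators
(earliest year as reference). Spline boundary knots sit at the observed
range with internal knots at equally spaced quantiles. The conception-month
spline is non-cyclic by default — December-January continuity is absorbed
well enough at df 4 — with a Fourier (periodic) basis available via
`term_ns(..., cyclic = TRUE)`. Exposure odds ratios are invariant to all
reference choices. Covariates are entered per event (each event's own
window means, age, conception month and year), so they vary within sets and
stay identifiable.

Nonlinear exposure-response replaces the linear exposure with a natural
spline (df 3 by default) and reports the log-OR curve relative to zero
exposure, with delta-method pointwise intervals, on 50 equally spaced
points from 0 to the 99th percentile of exposure; a categorical-bins
variant uses quartile cuts of the positive exposures. Departure from
linearity is judged by a likelihood-ratio test against the linear fit.

### Subgroup interactions

Subgroup indicators enter only through interactions with exposure: their
main effects are set-constant and cancel. For mother-level indicators
(education, residence) every event carries the case's — equivalently the
mother's — value (`define_by = "case"`). Maternal age is different: it
evolves across a mother's pregnancies, and susceptibility plausibly belongs
to the pregnancy, not the mother. The age interaction therefore uses each
event's own age group (`define_by = "event"`, bands <30, 30-34, >=35).
This was a genuinely open choice; the deciding argument is internal
consistency — the synthetic generator injects age-specific effects per
pregnancy, and assigning the case's band to a whole set demonstrably
attenuates the oldest band's estimate when sets straddle bands.
Heterogeneity is tested by a likelihood-ratio test of the per-group-slope
model against the common-slope model.

## Attributable fractions

For each source, `AF = 1 - 1/exp(beta * (mean - TMREL))`, with the mean
exposure taken over all analysed events (cases and controls), TMREL 0
ug/m3 for fire PM2.5 and 10 ug/m3 (the WHO air-quality guideline) for
non-fire PM2.5. A mean below the TMREL is clamped — no protective
attribution. Interval bounds substitute the Wald bounds of beta, which is
valid because the transform is monotone. The fire share of the PM2.5-linked
burden is `AF_fire / (AF_fire + AF_nonfire)`; the per-unit excess-risk
comparison is made on the OR-minus-one scale, the scale on which per-ug/m3
excess risks are conventionally quoted.

## The synthetic world

The generator produces data with exactly the statistical structure the
analysis assumes, so that parameter recovery is a meaningful validation.

**Fields.** The fire component is a sum of Gaussian spatial kernels around
hotspot centers (overlap saturating at 1), a burning-season weight peaking
at configured months (March, April, October by default), and independent
lognormal monthly multipliers (sdlog 0.8, mean fixed at one so a hotspot's
peak-season expectation equals its amplitude, 5 ug/m3 by default) plus a
small domain-wide background (0.3 ug/m3) standing in for transported smoke.
The non-fire surface is a smooth low-order spatial polynomial around 52
ug/m3 with a mild (15%) seasonal cycle. The with-fire field is the sum of
the two, so source additivity is exact. Burned-area fraction is nonzero
only inside hotspot footprints, which makes "fire PM2.5 with zero local
burned area" — the transported-smoke sensitivity subset — a real stratum.
The satellite reference is the annual-mean with-fire field, downscaled,
times lognormal noise (sd 0.05).

**Histories.** Mothers sit at uniform random locations; age at first
conception is normal (mean 21.5, SD 5, clipped to 15-40), chosen so the
case age distribution lands near the survey descriptives (mean about 26,
SD about 6, with appreciable mass at 35 and over). Pregnancy counts are
1 + Poisson(3); inter-pregnancy gaps 9-40 months. Each pregnancy's loss
indicator follows

\[ \mathrm{logit}(p) = \alpha_i + \beta_{fire}\bar X_{fire}
   + \beta_{nonfire}(\bar X_{nonfire} - 52) + \text{age band} +
   \beta_T(\bar T - 26) + \beta_H(\bar H - 60) + \text{season} +
   \text{trend}, \]

with mother intercepts \(\alpha_i \sim N(\mathrm{logit}(0.18), 1)\).
Centering the nuisance covariates is absorbed by the intercept and leaves
the matched-design truth unchanged; it simply makes the intercept mean
control the marginal loss rate (about 19%). The draw is a uniform
threshold, so raising an effect under a fixed seed can only add losses —
the monotonicity property asserted in tests.

Two generator choices matter for unbiased recovery and deserve emphasis:

- *one risk-window length per mother.* The candidate loss gestation is
  drawn once per mother (from a 1-9 month mixture spanning the
  miscarriage/stillbirth split; the survey literature does not pin this
  distribution down, so it is configuration, not constant) and defines the
  exposure window of **all** her pregnancies. The analysis averages
  controls over the case's gestation length — with a per-mother window
  length the generating model and the fitted model coincide, so
  conditional-logit recovery is exact up to sampling error. Drawing a
  fresh window per pregnancy would put deliberate measurement error into
  the covariates and attenuate every recovered effect.
- *the same exposure chain.* Window exposures that drive the simulated
  outcomes are computed through the identical
  downscale-calibrate-decompose path the analysis later applies, at the
  same fine cells, so there is no exposure-model mismatch to attenuate
  recovery.

A small deliberate imperfection remains: the age covariate used when an
outcome is drawn is the age at the candidate window's end, while the
analysis recomputes a live birth's age at its actual termination. The two
can differ by up to 8 months across 5-year bands; the effect on exposure
coefficients is negligible, and it keeps the analysis side honest about
recomputing ages per event.

**What the generator does not emulate:** geographic realism (no
population clustering, coastlines, or country borders), recall
misclassification of outcomes or gestation lengths, survey sampling
weights, self-induced abortions misreported as losses, within-month timing
of events, or correlated measurement error between the simulation fields
and the satellite reference. Passing recovery tests therefore validates
the estimator and the pipeline plumbing, not robustness to those
real-data pathologies.

## Numerical and procedural decisions

- Case ties (two losses terminating in the same month): the first record
  in input order wins, deterministically; affected mothers are reported.
- "Healthy newborns who survived more than 12 months": survival months
  strictly greater than 12 with known status; unknown survival excludes a
  control under this flag only.
- Recall flags compare whole months: survey minus termination < 12 n.
- Transported-fire takes the strictest reading: zero burned fraction in
  every month of every window of the set, at the mother's cell.
- Parity matching: all members nulliparous with every control after the
  case, or all multiparous.
- Controls need valid exposure, not in-period conception; the study period
  restricts case selection only.
- `eta` is computed per fine cell and year; years with missing months are
  an error rather than a guess.
- Newton convergence: relative log-likelihood change < 1e-10, at most 50
  iterations, 10 step-halvings; within-set softmax uses a per-set max
  shift for overflow safety.
- All randomness descends from one root seed, split per stage with fixed
  offsets; identical config and seed give byte-identical outputs end to
  end, including the run manifest (minus its timestamp).

## Validation problem sizes

The package's own validation studies (the acceptance test suite and
`scripts/acceptance.R`) use: about 48,000 mothers yielding about 20,000
matched sets for main-effect recovery; 120,000 mothers (about 50,000 sets)
for the age-interaction study, where the oldest band is thinnest and the
heterogeneity test needs its power; 200 replicates of roughly 5,000 sets
for Wald coverage; and small hand-built fixtures for the exact oracles
(discordant-pair closed form, refined grid search, exposure identities).

## Known limitations

- The conditional likelihood assumes outcomes independent across a
  mother's pregnancies given covariates and her intercept; carry-over
  effects (a loss raising subsequent risk) are neither simulated nor
  modelled.
- Wald intervals and the inverse observed information are asymptotic; at a
  few hundred sets the subgroup heterogeneity test runs visibly
  anti-conservative (observed around 10% size at 150 sets, nominal at 400
  and above), so subgroup analyses of small subsets deserve caution.
- No robust/sandwich variances, random-effects alternatives, or exact
  permutation inference; no imputation of missing gestation lengths; no
  survey weights.
- AF intervals propagate only the uncertainty in beta, not in the mean
  exposure.
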