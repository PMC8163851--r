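#' Attributable fraction of pregnancy loss for a PM2.5 source
#'
#' Fraction of the outcome burden attributable to exposure above a reference
#' level, from the log-linear association:
#' \deqn{AF = 1 - 1/\exp[\beta (\bar{PM}_{2.5} - TMREL)]}
#' where \eqn{\bar{PM}_{2.5}} is the mean exposure over the analysed samples
#' (cases and controls) and TMREL the theoretical minimum risk exposure
#' level — 0 ug/m3 for fire PM2.5 and 10 ug/m3 (the WHO air-quality
#' guideline) for non-fire PM2.5. A mean below the TMREL is clamped to the
#' TMREL before applying the formula: no protective attribution. Confidence
#' bounds substitute the Wald CI bounds of beta (the formula is monotone in
#' beta).
#'
#' @param beta log-odds per 1 ug/m3.
#' @param mean_exposure mean exposure (ug/m3) in the analysed samples.
#' @param tmrel theoretical minimum risk exposure level (ug/m3).
#' @param beta_ci optional `c(low, high)` CI of beta.
#' @return list with `af` and, when `beta_ci` is given, `af_low`, `af_high`.
#' @examples
#' attributable_fraction(log(1.051), 1.2, 0)   # ~0.058
#' @export
attributable_fraction <- function(beta, mean_exposure, tmrel = 0,
                                  beta_ci = NULL) {
  if (mean_exposure < 0) stop("mean exposure must be non-negative")
  delta <- max(mean_exposure - tmrel, 0)
  out <- list(af = 1 - exp(-beta * delta))
  if (!is.null(beta_ci)) {
    out$af_low <- 1 - exp(-beta_ci[1] * delta)
    out$af_high <- 1 - exp(-beta_ci[2] * delta)
  }
  out
}

#' Comparative impact of fire versus non-fire PM2.5
#'
#' Two summaries of source importance: the fire share of the PM2.5-linked
#' outcome burden, \eqn{AF_{fire}/(AF_{fire}+AF_{nonfire})}, and the
#' per-unit excess-risk ratio on the odds-ratio-minus-one scale,
#' \eqn{[(e^{\beta_{fire}} - 1)/(e^{\beta_{nonfire}} - 1) - 1]}, reported as
#' a percentage (how much higher the per-ug/m3 excess risk of fire PM2.5 is).
#'
#' @param af_fire,af_nonfire attributable fractions for the two sources,
#'   computed on the same cohort.
#' @param beta_fire,beta_nonfire the per-ug/m3 log-odds coefficients.
#' @return list with `fire_share`, `nonfire_share`, and
#'   `excess_risk_ratio_pct`.
#' @examples
#' compare_sources(0.058, 0.44, log(1.051), log(1.014))
#' @export
compare_sources <- function(af_fire, af_nonfire, beta_fire, beta_nonfire) {
  if (af_fire == 0 && af_nonfire == 0)
    stop("both attributable fractions are zero; shares undefined")
  share <- af_fire / (af_fire + af_nonfire)
  err <- (expm1(beta_fire) / expm1(beta_nonfire) - 1) * 100
  list(fire_share = share, nonfire_share = 1 - share,
       excess_risk_ratio_pct = err)
}

#' Impact accounting from a fitted model and cohort
#'
#' Computes both sources' attributable fractions from a mutually adjusted
#' fit and the cohort's mean exposures (over cases and controls), overall or
#' stratified by a grouping column (e.g. a country analogue), and the
#' fire-versus-non-fire comparison.
#'
#' @param fit a [fit_clogit()] result containing `fire` and `nonfire` terms.
#' @param cohort the analysis data the model was fitted to.
#' @param tmrel_fire,tmrel_nonfire reference exposures (ug/m3).
#' @param by optional stratification column of `cohort`.
#' @return data.frame with one row per source (and stratum): beta, OR, mean
#'   exposure, TMREL, AF with CI, burden share; attribute
#'   `"comparison"` holds the [compare_sources()] summary for the overall
#'   rows.
#' @export
impact_summary <- function(fit, cohort, tmrel_fire = 0, tmrel_nonfire = 10,
                           by = NULL) {
  ot <- fit$or_table
  need <- c("fire", "nonfire")
  if (!all(need %in% ot$term))
    stop("fit must contain 'fire' and 'nonfire' exposure terms")
  strata <- list(overall = seq_len(nrow(cohort)))
  if (!is.null(by))
    strata <- c(strata, split(seq_len(nrow(cohort)), cohort[[by]]))
  rows <- NULL
  for (s in names(strata)) {
    sel <- strata[[s]]
    for (src in need) {
      r <- ot[ot$term == src, ]
      tm <- if (src == "fire") tmrel_fire else tmrel_nonfire
      mexp <- mean(cohort[[src]][sel])
      ci <- c(r$beta - 1.959964 * r$se, r$beta + 1.959964 * r$se)
      af <- attributable_fraction(r$beta, mexp, tm, beta_ci = ci)
      rows <- rbind(rows, data.frame(
        stratum = s, source = src, beta = r$beta, or = r$or,
        mean_exposure = mexp, tmrel = tm, af = af$af,
        af_low = af$af_low, af_high = af$af_high))
    }
  }
  rows$share <- NA_real_
  for (s in unique(rows$stratum)) {
    i <- rows$stratum == s
    tot <- sum(rows$af[i])
    if (tot > 0) rows$share[i] <- rows$af[i] / tot
  }
  bf <- ot$beta[ot$term == "fire"]
  bn <- ot$beta[ot$term == "nonfire"]
  ov <- rows[rows$stratum == names(strata)[1], ]
  attr(rows, "comparison") <- compare_sources(
    ov$af[ov$source == "fire"], ov$af[ov$source == "nonfire"], bf, bn)
  rows
}
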