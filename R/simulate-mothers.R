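#' Simulate mother reproductive histories
#'
#' Draws a population of mothers at random locations in the domain and
#' generates their pregnancy events so that the loss probability follows the
#' mother-stratified logistic model the matched analysis assumes:
#' \deqn{logit(p) = \alpha_i + \beta_{fire} \bar X_{fire} +
#'   \beta_{nonfire} \bar X_{nonfire} + age\ band + weather + season + trend}
#' where the exposure covariates are gestational-window means computed
#' through the same downscale-calibrate-decompose chain the analysis applies
#' ([extract_exposure()], [window_means()]).
#'
#' One candidate loss-gestation length is drawn per mother and defines the
#' risk window of all her pregnancies, so that the analysis rule — averaging
#' controls over a window of the case's gestation length — coincides with the
#' generating model and effect recovery is unbiased. A pregnancy that
#' resolves as a loss keeps that gestation; a live birth gestates 9 months.
#' When `config$age_fire_log_or` is set, the fire coefficient varies by
#' maternal age group (<30, 30-34, >=35) instead of being constant.
#'
#' @param config a [world_config()].
#' @param fields the [simulate_fields()] output for the same config.
#' @param return_series also return the internally computed exposure series
#'   (as attribute `"exposure_series"`), saving a second extraction pass when
#'   the analysis continues on the same mothers.
#' @return data.frame of pregnancy events (one row each) with columns
#'   `mother_id`, `lat`, `lon`, `birth_cohort_cmc`, `survey_cmc`,
#'   `event_index`, `outcome` ("loss" or "live_birth"), `conception_cmc`,
#'   `termination_cmc`, `gestation_months`, `maternal_age_years`,
#'   `parity_before`, `singleton`, `infant_survival_months`, `education`,
#'   `residence`. Mothers drawn with zero pregnancies are flagged in
#'   `attr(, "zero_pregnancy_mothers")`.
#' @examples
#' cfg <- world_config(n_mothers = 50, lat_range = c(10, 14),
#'                     lon_range = c(70, 74), rng_seed = 3)
#' ev <- simulate_mothers(cfg, simulate_fields(cfg))
#' table(ev$outcome)
#' @export
simulate_mothers <- function(config, fields, return_series = FALSE) {
  cfg <- validate_world_config(config)
  set.seed(stage_seed(cfg$rng_seed, "mothers"))
  months <- fields$months
  first_m <- months[1]
  last_m <- months[length(months)]
  n <- cfg$n_mothers

  mothers <- data.frame(
    mother_id = seq_len(n),
    lat = stats::runif(n, cfg$lat_range[1], cfg$lat_range[2]),
    lon = stats::runif(n, cfg$lon_range[1], cfg$lon_range[2]),
    alpha = stats::rnorm(n, cfg$intercept_mean, cfg$intercept_sd),
    case_gestation = sample(1:9, n, replace = TRUE,
                            prob = cfg$loss_gestation_probs),
    survey_cmc = last_m + sample(1:12, n, replace = TRUE),
    education = sample(c("none", "primary", "secondary+"), n, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)),
    residence = sample(c("rural", "urban"), n, replace = TRUE,
                       prob = c(0.65, 0.35)))
  n_preg <- stats::rpois(n, cfg$mean_pregnancies - 1) + 1L
  # a small fraction of zero-pregnancy mothers, permitted but flagged
  zero <- stats::runif(n) < 0.01
  n_preg[zero] <- 0L

  # first conception early enough that several pregnancies fit the period
  # age at first conception chosen so the case age distribution approximates
  # survey descriptives (mean age at loss ~26, SD ~6, appreciable mass >=35)
  age1 <- pmin(pmax(stats::rnorm(n, 21.5, 5), 15), 40)
  conc1 <- first_m + floor(stats::runif(n, 0, 0.35 * (last_m - first_m)))
  birth_cohort <- conc1 - round(age1 * 12)
  mothers$birth_cohort_cmc <- birth_cohort

  # expand pregnancies: conception spacing = previous gestation + gap
  idx <- rep.int(seq_len(n), n_preg)
  ord <- sequence(n_preg)
  n_ev <- length(idx)
  gap <- sample(9:40, n_ev, replace = TRUE)
  conc <- integer(n_ev)
  ev_of_mother <- split(seq_len(n_ev), idx)
  for (m in which(n_preg > 0L)) {
    rows <- ev_of_mother[[as.character(m)]]
    c_ <- conc1[m]
    for (r in rows) {
      conc[r] <- c_
      c_ <- c_ + 9L + gap[r]       # worst-case spacing; refined after outcomes
    }
  }
  keep <- conc <= last_m - 8L       # window of up to 9 months must be covered
  idx <- idx[keep]; ord <- ord[keep]; conc <- conc[keep]
  n_ev <- length(idx)

  series <- extract_exposure(fields, data.frame(
    id = mothers$mother_id, lat = mothers$lat, lon = mothers$lon))
  gi <- mothers$case_gestation[idx]
  w <- window_means(series, idx, conc, gi,
                    vars = c("fire", "nonfire", "temperature", "humidity"))

  term_cand <- conc + gi - 1L
  age_ev <- floor((term_cand - birth_cohort[idx]) / 12)
  band <- age_band(age_ev)
  moy <- cmc_month(conc)
  yr <- cmc_year(conc)

  if (is.null(cfg$age_fire_log_or)) {
    b_fire <- rep(cfg$true_log_or_fire, n_ev)
  } else {
    grp <- age_group3(age_ev)
    b_fire <- unname(cfg$age_fire_log_or[grp])
  }
  # covariates centered at their configured reference means so the intercept
  # distribution controls the marginal loss rate; centering is absorbed by
  # the mother intercept and leaves the matched-design truth unchanged
  lp <- mothers$alpha[idx] +
    b_fire * w$fire +
    cfg$true_log_or_nonfire * (w$nonfire - cfg$nonfire_mean) +
    cfg$age_effect[band] - mean(cfg$age_effect) +
    cfg$temp_effect * (w$temperature - cfg$temp_mean) +
    cfg$humidity_effect * (w$humidity - cfg$humidity_mean) +
    cfg$seasonal_amplitude * sin(2 * pi * (moy - 1) / 12) +
    cfg$trend_slope * (yr - cfg$years[1])
  # uniform-threshold draw: with a fixed seed, raising an effect never turns
  # a loss back into a live birth (monotone coupling)
  loss <- stats::runif(n_ev) < stats::plogis(lp)

  gestation <- ifelse(loss, gi, 9L)
  termination <- conc + gestation - 1L
  age_years <- floor((termination - birth_cohort[idx]) / 12)

  surv <- rep(NA_integer_, n_ev)
  lb <- !loss
  surv_class <- stats::runif(sum(lb))
  surv[lb] <- ifelse(surv_class < 0.9, 13L + sample(0:47, sum(lb), TRUE),
                     sample(0:12, sum(lb), TRUE))
  surv[lb][surv_class > 0.98] <- NA_integer_   # unknown survival status

  events <- data.frame(
    mother_id = mothers$mother_id[idx],
    lat = mothers$lat[idx],
    lon = mothers$lon[idx],
    birth_cohort_cmc = birth_cohort[idx],
    survey_cmc = mothers$survey_cmc[idx],
    event_index = ord,
    outcome = ifelse(loss, "loss", "live_birth"),
    conception_cmc = conc,
    termination_cmc = termination,
    gestation_months = gestation,
    maternal_age_years = age_years,
    singleton = stats::rbinom(n_ev, 1L, 0.98) == 1L,
    infant_survival_months = surv,
    education = mothers$education[idx],
    residence = mothers$residence[idx])
  events <- events[order(events$mother_id, events$conception_cmc), ]
  events$parity_before <- stats::ave(
    as.integer(events$outcome == "live_birth"), events$mother_id,
    FUN = function(x) cumsum(c(0L, x[-length(x)])))
  events$event_index <- stats::ave(events$mother_id, events$mother_id,
                                   FUN = seq_along)
  rownames(events) <- NULL
  attr(events, "zero_pregnancy_mothers") <- mothers$mother_id[zero]
  attr(events, "config") <- cfg
  if (return_series) attr(events, "exposure_series") <- series
  events
}

# Six maternal-age bands used for covariate adjustment; first is reference.
age_band <- function(age) {
  findInterval(age, c(-Inf, 20, 25, 30, 35, 40))
}

age_band_label <- function(band) {
  c("<20", "20-24", "25-29", "30-34", "35-39", ">=40")[band]
}

# Three age groups used in the exposure-by-age interaction analysis.
age_group3 <- function(age) {
  c("<30", "30-34", ">=35")[findInterval(age, c(-Inf, 30, 35))]
}

#' Write / read pregnancy-event tables
#'
#' One row per pregnancy event, the documented CSV schema shared by the
#' synthetic generator and user-prepared survey extracts.
#'
#' @param events event data.frame (see [simulate_mothers()]).
#' @param path CSV path.
#' @return `read_events_csv()` returns the event data.frame.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mother_id", "lat", "lon", "outcome", "conception_cmc",
            "termination_cmc", "gestation_months", "maternal_age_years",
            "survey_cmc")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event table lacks required columns: ", paste(miss, collapse = ", "))
  bad <- ev$termination_cmc - ev$conception_cmc + 1L != ev$gestation_months
  if (any(bad, na.rm = TRUE))
    stop(sum(bad, na.rm = TRUE),
         " events violate termination = conception + gestation - 1")
  ev
}
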