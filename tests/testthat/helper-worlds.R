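# Shared fixture builders. Everything is generated in code at test time.

# A small, fast world: 8 x 8 coarse cells, 15 years, a few hundred mothers.
tiny_world <- function(seed = 101, n_mothers = 400, ...) {
  world_config(n_mothers = n_mothers, lat_range = c(10, 18),
               lon_range = c(70, 78), n_hotspots = 2, rng_seed = seed, ...)
}

# Hand-built exposure series on a constant field: every variable constant,
# so window means are predictable. Months cover 2000-2014.
constant_series <- function(ids, fire = 2, nonfire = 50, temperature = 25,
                            humidity = 60, burned = 0, dry = 0) {
  months <- seq.int(cmc(2000, 1), cmc(2014, 12))
  n <- length(ids); m <- length(months)
  mk <- function(v) matrix(v, n, m)
  structure(list(ids = ids, months = months, years = 2000:2014,
                 total = mk(fire + nonfire), fire = mk(fire),
                 nonfire = mk(nonfire), burned_frac = mk(burned),
                 dry_matter = mk(dry), temperature = mk(temperature),
                 humidity = mk(humidity),
                 eta = matrix(1, n, 15)),
            class = "exposure_series")
}

# One pregnancy-event row with sensible defaults.
event_row <- function(mother_id, outcome, conception, gestation,
                      lat = 12, lon = 72, age = 25, parity = 0,
                      singleton = TRUE, survival = 24, survey = cmc(2015, 6)) {
  data.frame(mother_id = mother_id, lat = lat, lon = lon,
             birth_cohort_cmc = conception - age * 12L,
             survey_cmc = survey, event_index = 1L, outcome = outcome,
             conception_cmc = conception,
             termination_cmc = conception + gestation - 1L,
             gestation_months = gestation, maternal_age_years = age,
             singleton = singleton, infant_survival_months = survival,
             education = "primary", residence = "rural",
             parity_before = parity)
}

# Matched-set data drawn straight from the conditional model: covariates per
# event, the case chosen by within-set softmax of the true linear predictor.
# This is the exact sampling distribution the conditional likelihood models,
# so it serves as a fast generator for estimator properties.
conditional_sets <- function(n_sets, beta, set_size = 3,
                             draw_x = function(n) cbind(x1 = rnorm(n)),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sizes <- if (length(set_size) == 1) rep(set_size, n_sets) else
    sample(set_size, n_sets, replace = TRUE)
  sid <- rep.int(seq_len(n_sets), sizes)
  X <- draw_x(length(sid))
  eta <- drop(X %*% beta)
  case <- logical(length(sid))
  off <- c(0L, cumsum(sizes))
  for (s in seq_len(n_sets)) {
    j <- (off[s] + 1L):off[s + 1L]
    w <- exp(eta[j] - max(eta[j]))
    case[j[sample.int(length(j), 1L, prob = w)]] <- TRUE
  }
  d <- data.frame(set_id = sid, role = ifelse(case, "case", "control"))
  cbind(d, as.data.frame(X))
}

# Dense grid search of the exact conditional log-likelihood with iterative
# refinement (oracle for the Newton fitter; independent of its score and
# information algebra and of its estimates). Handles 1 or 2 coefficients.
clogit_grid_search <- function(X, set, case, half_width = 2, n_grid = 41,
                               refinements = 5) {
  p <- ncol(X)
  groups <- split(seq_along(set), set)
  ll <- function(beta) {
    eta <- drop(X %*% beta)
    s <- 0
    for (g in groups) s <- s + eta[g][case[g]] - log(sum(exp(eta[g])))
    s
  }
  center <- rep(0, p)
  hw <- rep(half_width, p)
  for (it in seq_len(refinements + 1)) {
    grids <- lapply(seq_len(p), function(j)
      seq(center[j] - hw[j], center[j] + hw[j], length.out = n_grid))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1, ll)
    center <- pts[which.max(vals), ]
    hw <- hw * 2.5 / (n_grid - 1)     # zoom just beyond one grid step
  }
  list(beta = unname(center), loglik = max(vals))
}
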