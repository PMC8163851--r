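#' Configuration of the synthetic study world
#'
#' Bundles every knob of the synthetic-data generator: the spatial grid, the
#' study period, the population size, and the true effect sizes on the
#' log-odds scale that downstream model fitting should recover. Defaults
#' emulate a South-Asia-like domain: a smooth, high non-fire PM2.5 background
#' (tens of ug/m3), a right-skewed fire component concentrated around a few
#' hotspots and peaking in the configured burning-season months, and
#' reproductive histories over 2000-2014 whose loss probability follows a
#' mother-stratified logistic model.
#'
#' @param lat_range,lon_range extent of the domain in degrees (cell centers
#'   fall inside).
#' @param coarse_res coarse simulation-grid resolution in degrees (the
#'   synthetic analogue of a chemical-transport-model grid).
#' @param fine_res fine grid resolution in degrees for the satellite reference
#'   and downscaled exposure (0.1 by convention).
#' @param years study period as `c(first, last)` calendar year.
#' @param n_mothers number of mothers simulated.
#' @param true_log_or_fire true log-odds of pregnancy loss per 1 ug/m3
#'   window-mean fire PM2.5.
#' @param true_log_or_nonfire true log-odds per 1 ug/m3 non-fire PM2.5.
#' @param age_fire_log_or optional named vector of age-group-specific fire
#'   log-odds (groups `"<30"`, `"30-34"`, `">=35"`); when supplied it replaces
#'   `true_log_or_fire` with an exposure-by-age interaction.
#' @param age_effect log-odds offsets for the six maternal-age bands
#'   (`<20, 20-24, 25-29, 30-34, 35-39, >=40`), first band is reference.
#' @param temp_effect,humidity_effect log-odds per unit window-mean
#'   temperature (degC) and relative humidity (%).
#' @param seasonal_amplitude amplitude of a sinusoidal conception-month effect
#'   on the log-odds scale.
#' @param trend_slope secular log-odds trend per year.
#' @param intercept_mean,intercept_sd mean and SD of the mother-specific
#'   baseline intercept on the logit scale. The matched design cancels the
#'   intercepts, so the SD is a nuisance parameter.
#' @param fire_meanlog,fire_sdlog parameters of the lognormal monthly
#'   multiplier of the fire field; the default `meanlog = -sdlog^2/2` makes
#'   the multiplier mean one, so a hotspot's peak-season mean equals its
#'   amplitude.
#' @param fire_amplitude peak-season mean fire PM2.5 (ug/m3) at a hotspot
#'   center.
#' @param fire_hotspots data.frame with columns `lat`, `lon` of hotspot
#'   centers; `NULL` draws `n_hotspots` uniformly over the domain.
#' @param n_hotspots number of hotspots when `fire_hotspots` is `NULL`.
#' @param fire_sigma spatial kernel scale of a hotspot (degrees).
#' @param fire_peak_months months (1-12) at which the burning-season weight
#'   peaks.
#' @param fire_background domain-wide baseline fire PM2.5 (ug/m3) sharing the
#'   seasonal cycle, emulating regionally transported smoke.
#' @param nonfire_mean domain-mean non-fire PM2.5 (ug/m3).
#' @param nonfire_spatial_sd scale of the smooth spatial variation of the
#'   non-fire surface.
#' @param nonfire_seasonal_frac fractional amplitude of the mild non-fire
#'   seasonal cycle.
#' @param satellite_noise_sd lognormal SD of the multiplicative noise linking
#'   the annual satellite reference to the annual-mean with-fire field.
#' @param burned_frac_max maximum burned-area fraction (%) near a hotspot at
#'   peak season.
#' @param temp_mean,temp_seasonal_amp,temp_lat_gradient,temp_noise_sd
#'   temperature field parameters (degC).
#' @param humidity_mean,humidity_seasonal_amp,humidity_noise_sd relative
#'   humidity field parameters (%).
#' @param mean_pregnancies mean number of pregnancies per mother (at least
#'   one is always drawn).
#' @param loss_gestation_probs probabilities of gestation lengths 1-9 months
#'   for pregnancy losses; the default mixture puts most mass below 5 months
#'   (miscarriage) with a stillbirth tail, spanning the <5 / >=5 month split.
#' @param rng_seed integer seed; fixed seed implies byte-identical output.
#' @return an object of class `world_config` (a validated list).
#' @examples
#' cfg <- world_config(n_mothers = 100, rng_seed = 1)
#' cfg$years
#' @export
world_config <- function(lat_range = c(6, 34),
                         lon_range = c(62, 94),
                         coarse_res = 1,
                         fine_res = 0.1,
                         years = c(2000, 2014),
                         n_mothers = 2000,
                         true_log_or_fire = log(1.051),
                         true_log_or_nonfire = log(1.014),
                         age_fire_log_or = NULL,
                         age_effect = c(0, 0.10, 0.20, 0.35, 0.55, 0.80),
                         temp_effect = 0.02,
                         humidity_effect = 0.005,
                         seasonal_amplitude = 0.1,
                         trend_slope = -0.02,
                         intercept_mean = stats::qlogis(0.18),
                         intercept_sd = 1,
                         fire_sdlog = 0.8,
                         fire_meanlog = -fire_sdlog^2 / 2,
                         fire_amplitude = 5,
                         fire_hotspots = NULL,
                         n_hotspots = 8,
                         fire_sigma = 3,
                         fire_peak_months = c(3, 4, 10),
                         fire_background = 0.3,
                         nonfire_mean = 52,
                         nonfire_spatial_sd = 12,
                         nonfire_seasonal_frac = 0.15,
                         satellite_noise_sd = 0.05,
                         burned_frac_max = 40,
                         temp_mean = 26, temp_seasonal_amp = 6,
                         temp_lat_gradient = -0.4, temp_noise_sd = 1,
                         humidity_mean = 60, humidity_seasonal_amp = 15,
                         humidity_noise_sd = 3,
                         mean_pregnancies = 4,
                         loss_gestation_probs = c(0.08, 0.14, 0.20, 0.22,
                                                  0.12, 0.09, 0.07, 0.05, 0.03),
                         rng_seed = 20140101) {
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  validate_world_config(cfg)
}

validate_world_config <- function(cfg) {
  stopifnot(length(cfg$lat_range) == 2L, diff(cfg$lat_range) >= 0,
            length(cfg$lon_range) == 2L, diff(cfg$lon_range) >= 0)
  if (cfg$coarse_res <= 0 || cfg$fine_res <= 0) stop("resolution must be > 0")
  n_cells <- floor(diff(cfg$lat_range) / cfg$coarse_res) *
    floor(diff(cfg$lon_range) / cfg$coarse_res)
  if (n_cells < 1) stop("grid extent too small: zero coarse cells")
  if (cfg$n_mothers < 1) stop("n_mothers must be positive")
  stopifnot(length(cfg$years) == 2L, cfg$years[1] <= cfg$years[2])
  if (length(cfg$age_effect) != 6L)
    stop("age_effect needs one offset per maternal-age band (6 bands)")
  if (!is.null(cfg$age_fire_log_or)) {
    if (!all(c("<30", "30-34", ">=35") %in% names(cfg$age_fire_log_or)))
      stop('age_fire_log_or must name groups "<30", "30-34", ">=35"')
  }
  p <- cfg$loss_gestation_probs
  if (length(p) != 9L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("loss_gestation_probs must be 9 non-negative values summing to 1")
  if (is.null(cfg$rng_seed) || is.na(cfg$rng_seed))
    stop("rng_seed is mandatory")
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg
}

#' Read / write a world configuration as YAML
#'
#' Reads a YAML mapping whose keys are [world_config()] arguments. The seed
#' is mandatory: a config without `rng_seed` is rejected rather than silently
#' defaulted, so every simulated world is reproducible from its config file.
#' `write_world_config()` serialises with 17 significant digits so every
#' double survives the round trip bit for bit and a re-simulated world is
#' identical.
#'
#' @param path path to a YAML file.
#' @return a `world_config` object.
#' @export
read_world_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$rng_seed)) stop("config file must set rng_seed")
  known <- names(formals(world_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$age_fire_log_or)) raw$age_fire_log_or <- unlist(raw$age_fire_log_or)
  for (f in c("lat_range", "lon_range", "years", "age_effect",
              "loss_gestation_probs"))
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  if (!is.null(raw$fire_hotspots))
    raw$fire_hotspots <- as.data.frame(lapply(as.data.frame(raw$fire_hotspots), unlist))
  do.call(world_config, raw)
}

#' @rdname read_world_config
#' @param config a `world_config` object.
#' @export
write_world_config <- function(config, path) {
  writeLines(yaml::as.yaml(unclass_config(config), precision = 17), path)
  invisible(path)
}

#' @export
print.world_config <- function(x, ...) {
  cat("Synthetic world configuration\n")
  cat(sprintf("  domain: lat %g..%g, lon %g..%g (coarse %g deg, fine %g deg)\n",
              x$lat_range[1], x$lat_range[2], x$lon_range[1], x$lon_range[2],
              x$coarse_res, x$fine_res))
  cat(sprintf("  period: %d-%d; mothers: %d; seed: %d\n",
              x$years[1], x$years[2], x$n_mothers, x$rng_seed))
  if (is.null(x$age_fire_log_or)) {
    cat(sprintf("  true OR per 1 ug/m3: fire %.4f, non-fire %.4f\n",
                exp(x$true_log_or_fire), exp(x$true_log_or_nonfire)))
  } else {
    cat("  age-specific fire ORs:",
        paste(sprintf("%s %.3f", names(x$age_fire_log_or),
                      exp(x$age_fire_log_or)), collapse = ", "), "\n")
  }
  invisible(x)
}
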