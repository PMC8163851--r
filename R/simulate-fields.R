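#' Simulate gridded monthly environmental fields
#'
#' Generates the synthetic analogue of the exposure-assessment inputs: paired
#' with-fire / without-fire PM2.5 simulations on a coarse grid, burned-area
#' fraction and dry-matter emission indicators, temperature and humidity, and
#' an annual satellite-style PM2.5 reference on the fine grid.
#'
#' The fire component is a sum of Gaussian spatial kernels around hotspot
#' centers, modulated by a burning-season weight peaking at the configured
#' months and by independent lognormal monthly multipliers with mean one —
#' right-skewed, seasonally peaked, and spatially concentrated, in deliberate
#' contrast to the smooth low-order-polynomial non-fire surface with its mild
#' seasonal cycle. The with-fire field is exactly the without-fire field plus
#' the fire component, so source additivity holds by construction. The burned
#' fraction is nonzero only near hotspots; fire PM2.5 away from all hotspots
#' (the domain-wide background term) emulates transported smoke over
#' unburned land. The satellite reference is a noisy multiple of the
#' annual-mean with-fire field downscaled to the fine grid.
#'
#' @param config a [world_config()].
#' @return an object of class `field_stack`: coarse axes `lat`, `lon`, month
#'   codes `months`, matrices (`n_cells x n_months`, latitude varying
#'   fastest) `pm_wfire`, `pm_nofire`, `fire`, `burned_frac`, `dry_matter`,
#'   `temperature`, `humidity`; fine axes `fine_lat`, `fine_lon`; matrix
#'   `satellite` (`n_fine_cells x n_years`) with `years`; and the `config`.
#' @examples
#' f <- simulate_fields(world_config(n_mothers = 10, lat_range = c(10, 14),
#'                                   lon_range = c(70, 74), rng_seed = 7))
#' f
#' @export
simulate_fields <- function(config) {
  cfg <- validate_world_config(config)
  set.seed(stage_seed(cfg$rng_seed, "fields"))

  lat <- axis_centers(cfg$lat_range, cfg$coarse_res)
  lon <- axis_centers(cfg$lon_range, cfg$coarse_res)
  if (length(lat) == 0L || length(lon) == 0L)
    stop("grid extent too small: zero coarse cells")
  grid <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  n_cells <- nrow(grid)

  months <- seq.int(cmc(cfg$years[1], 1), cmc(cfg$years[2], 12))
  n_m <- length(months)
  moy <- cmc_month(months)

  # hotspot kernel (planar degrees; the synthetic world needs no geodesy here)
  hs <- cfg$fire_hotspots
  if (is.null(hs)) {
    hs <- data.frame(
      lat = stats::runif(cfg$n_hotspots, cfg$lat_range[1], cfg$lat_range[2]),
      lon = stats::runif(cfg$n_hotspots, cfg$lon_range[1], cfg$lon_range[2]))
  }
  kern <- rep(0, n_cells)
  for (h in seq_len(nrow(hs))) {
    d2 <- (grid$lat - hs$lat[h])^2 + (grid$lon - hs$lon[h])^2
    kern <- kern + exp(-d2 / (2 * cfg$fire_sigma^2))
  }
  kern_norm <- pmin(kern, 1)          # overlap saturates rather than stacks

  # burning-season weight: circular Gaussian bumps, value 1 at a peak month
  season_w <- vapply(1:12, function(m) {
    d <- abs(m - cfg$fire_peak_months)
    d <- pmin(d, 12 - d)
    max(exp(-d^2 / (2 * 1.2^2)))
  }, numeric(1))

  amp_cell <- cfg$fire_amplitude * kern_norm + cfg$fire_background
  lmult <- matrix(
    stats::rlnorm(n_cells * n_m, cfg$fire_meanlog, cfg$fire_sdlog),
    n_cells, n_m)
  fire <- (amp_cell %o% season_w[moy]) * lmult

  # smooth non-fire surface: low-order polynomial in normalised coordinates
  latn <- scale_unit(grid$lat, cfg$lat_range)
  lonn <- scale_unit(grid$lon, cfg$lon_range)
  cf <- stats::rnorm(5)
  poly_raw <- cf[1] * latn + cf[2] * lonn + cf[3] * latn * lonn +
    cf[4] * latn^2 + cf[5] * lonn^2
  poly_std <- if (n_cells > 1 && stats::sd(poly_raw) > 0) {
    (poly_raw - mean(poly_raw)) / stats::sd(poly_raw)
  } else {
    poly_raw * 0
  }
  nf_surface <- pmax(cfg$nonfire_mean + cfg$nonfire_spatial_sd * poly_std, 1)
  nf_season <- 1 + cfg$nonfire_seasonal_frac * cos(2 * pi * (moy - 1) / 12)
  nf_noise <- matrix(stats::rlnorm(n_cells * n_m, -0.05^2 / 2, 0.05),
                     n_cells, n_m)
  pm_nofire <- (nf_surface %o% nf_season) * nf_noise
  pm_wfire <- pm_nofire + fire

  # burned fraction: zero outside hotspot footprints (transported-smoke
  # cells) and zero everywhere when no open fires are simulated
  foot <- kern_norm * (kern_norm > 0.05) * as.numeric(cfg$fire_amplitude > 0)
  burned <- pmin((foot %o% season_w[moy]) * lmult * cfg$burned_frac_max, 100)
  dm_noise <- matrix(stats::rlnorm(n_cells * n_m, -0.3^2 / 2, 0.3),
                     n_cells, n_m)
  dry_matter <- 0.05 * burned * dm_noise   # kg DM m^-2 month^-1 scale

  temperature <- cfg$temp_mean +
    cfg$temp_lat_gradient * (grid$lat - mean(cfg$lat_range)) +
    rep(cfg$temp_seasonal_amp * cos(2 * pi * (moy - 6) / 12),
        each = n_cells) +
    stats::rnorm(n_cells * n_m, 0, cfg$temp_noise_sd)
  temperature <- matrix(temperature, n_cells, n_m)
  humidity <- cfg$humidity_mean +
    rep(cfg$humidity_seasonal_amp * cos(2 * pi * (moy - 8) / 12),
        each = n_cells) +
    stats::rnorm(n_cells * n_m, 0, cfg$humidity_noise_sd)
  humidity <- matrix(pmin(pmax(humidity, 1), 100), n_cells, n_m)

  # annual satellite reference on the fine grid
  fine_lat <- axis_centers(cfg$lat_range, cfg$fine_res)
  fine_lon <- axis_centers(cfg$lon_range, cfg$fine_res)
  years <- seq.int(cfg$years[1], cfg$years[2])
  yr_of <- cmc_year(months)
  ann_coarse <- matrix(vapply(years, function(y)
    rowMeans(pm_wfire[, yr_of == y, drop = FALSE]), numeric(n_cells)),
    nrow = n_cells)
  fq <- expand.grid(lat = fine_lat, lon = fine_lon, KEEP.OUT.ATTRS = FALSE)
  wts <- idw_weights(fq$lat, fq$lon, lat, lon)
  ann_fine <- idw_apply(wts, ann_coarse)
  sat_noise <- matrix(
    stats::rlnorm(length(ann_fine), -cfg$satellite_noise_sd^2 / 2,
                  cfg$satellite_noise_sd),
    nrow(ann_fine), ncol(ann_fine))
  satellite <- ann_fine * sat_noise

  structure(
    list(lat = lat, lon = lon, months = months,
         pm_wfire = pm_wfire, pm_nofire = pm_nofire, fire = fire,
         burned_frac = burned, dry_matter = dry_matter,
         temperature = temperature, humidity = humidity,
         fine_lat = fine_lat, fine_lon = fine_lon,
         satellite = satellite, years = years,
         hotspots = hs, config = cfg),
    class = "field_stack")
}

axis_centers <- function(range, res) {
  n <- floor(diff(range) / res + 1e-9)
  if (n < 1) return(numeric(0))
  range[1] + res * (seq_len(n) - 0.5)
}

scale_unit <- function(x, range) {
  if (diff(range) == 0) return(x * 0)
  (x - range[1]) / diff(range) * 2 - 1
}

#' @export
print.field_stack <- function(x, ...) {
  cat("Monthly field stack\n")
  cat(sprintf("  coarse grid: %d x %d cells (%g deg); fine grid: %d x %d (%g deg)\n",
              length(x$lat), length(x$lon), x$config$coarse_res,
              length(x$fine_lat), length(x$fine_lon), x$config$fine_res))
  cat(sprintf("  months: %d (%d-%d); variables: wfire, nofire, fire, burned_frac, dry_matter, temperature, humidity + annual satellite\n",
              length(x$months), x$config$years[1], x$config$years[2]))
  cat(sprintf("  mean with-fire PM2.5 %.1f ug/m3, mean fire component %.2f ug/m3\n",
              mean(x$pm_wfire), mean(x$fire)))
  invisible(x)
}
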