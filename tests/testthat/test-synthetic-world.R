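test_that("field simulation is deterministic and additive in sources", {
  cfg <- tiny_world(seed = 7)
  f1 <- simulate_fields(cfg)
  f2 <- simulate_fields(cfg)
  expect_identical(f1$pm_wfire, f2$pm_wfire)
  expect_identical(f1$satellite, f2$satellite)
  # with-fire = without-fire + fire component, exactly
  expect_equal(f1$pm_wfire, f1$pm_nofire + f1$fire, tolerance = 1e-15)
  expect_true(all(f1$pm_wfire >= 0) && all(f1$pm_nofire >= 0))
})

test_that("zero fire amplitude gives identical with/without-fire fields", {
  cfg <- tiny_world(seed = 8, fire_amplitude = 0, fire_background = 0)
  f <- simulate_fields(cfg)
  expect_identical(f$pm_wfire, f$pm_nofire)
  expect_true(all(f$fire == 0))
  expect_true(all(f$burned_frac == 0))
})

test_that("long-term hotspot mean at peak season matches the configured amplitude", {
  # hotspot on a cell center; lognormal multiplier has mean one, so the
  # Monte-Carlo expectation of the peak-month fire level at the center is
  # the amplitude. SE of the mean over 15 years x 3 peak months of a
  # lognormal(sdlog 0.8) is about amp * 0.95 / sqrt(45).
  amp <- 5
  cfg <- world_config(n_mothers = 1, lat_range = c(6, 14),
                      lon_range = c(66, 74),
                      fire_hotspots = data.frame(lat = 10.5, lon = 70.5),
                      fire_amplitude = amp, fire_background = 0,
                      fire_peak_months = c(3, 4, 10), rng_seed = 42)
  f <- simulate_fields(cfg)
  cell <- which(rep(f$lat, length(f$lon)) == 10.5 &
                  rep(f$lon, each = length(f$lat)) == 70.5)
  peak <- cmc_month(f$months) %in% c(3, 4, 10)
  m <- mean(f$fire[cell, peak])
  se <- amp * sqrt(exp(0.8^2) - 1) / sqrt(sum(peak))
  expect_lt(abs(m - amp), 3.5 * se)
})

test_that("satellite reference is a noisy multiple of the annual-mean with-fire field", {
  cfg <- tiny_world(seed = 9, satellite_noise_sd = 0.05)
  f <- simulate_fields(cfg)
  ann <- vapply(f$years, function(y)
    rowMeans(f$pm_wfire[, cmc_year(f$months) == y, drop = FALSE]),
    numeric(length(f$lat) * length(f$lon)))
  ann_fine <- idw_downscale(array(ann, c(length(f$lat), length(f$lon),
                                         length(f$years))),
                            f$lat, f$lon, f$fine_lat, f$fine_lon)
  ratio <- f$satellite / matrix(ann_fine, nrow(f$satellite))
  expect_gt(min(ratio), 0.7)
  expect_lt(max(ratio), 1.4)
  expect_lt(abs(mean(ratio) - 1), 0.01)
})

test_that("degenerate grids are rejected, a single cell is allowed", {
  expect_error(world_config(lat_range = c(10, 10.001), lon_range = c(70, 71),
                            coarse_res = 1, rng_seed = 1), "zero coarse cells")
  cfg1 <- world_config(lat_range = c(10, 11), lon_range = c(70, 71),
                       coarse_res = 1, n_mothers = 5, rng_seed = 1)
  f1 <- simulate_fields(cfg1)
  expect_equal(dim(f1$pm_wfire)[1], 1L)
})

test_that("mother histories satisfy the event invariants and are reproducible", {
  cfg <- tiny_world(seed = 11)
  f <- simulate_fields(cfg)
  ev1 <- simulate_mothers(cfg, f)
  ev2 <- simulate_mothers(cfg, f)
  expect_identical(ev1, ev2)
  expect_true(all(ev1$gestation_months >= 1 & ev1$gestation_months <= 9))
  expect_true(all(ev1$termination_cmc ==
                    ev1$conception_cmc + ev1$gestation_months - 1))
  expect_true(all(ev1$gestation_months[ev1$outcome == "live_birth"] == 9))
  # events temporally ordered within mother
  ord <- tapply(ev1$conception_cmc, ev1$mother_id,
                function(x) all(diff(x) > 0))
  expect_true(all(ord))
  expect_true(is.integer(attr(ev1, "zero_pregnancy_mothers")) ||
                is.numeric(attr(ev1, "zero_pregnancy_mothers")))
})

test_that("null-effect world reproduces the configured baseline loss rate", {
  cfg <- tiny_world(seed = 13, n_mothers = 1500,
                    true_log_or_fire = 0, true_log_or_nonfire = 0,
                    age_effect = rep(0, 6), temp_effect = 0,
                    humidity_effect = 0, seasonal_amplitude = 0,
                    trend_slope = 0, intercept_sd = 0,
                    intercept_mean = qlogis(0.2))
  f <- simulate_fields(cfg)
  ev <- simulate_mothers(cfg, f)
  p_hat <- mean(ev$outcome == "loss")
  se <- sqrt(0.2 * 0.8 / nrow(ev))
  expect_lt(abs(p_hat - 0.2), 4 * se)
})

test_that("raising the fire effect raises the number of losses under a fixed seed", {
  cfg0 <- tiny_world(seed = 17, n_mothers = 800, true_log_or_fire = 0)
  cfg1 <- tiny_world(seed = 17, n_mothers = 800, true_log_or_fire = 0.4)
  f <- simulate_fields(cfg0)
  n0 <- sum(simulate_mothers(cfg0, f)$outcome == "loss")
  n1 <- sum(simulate_mothers(cfg1, f)$outcome == "loss")
  expect_gt(n1, n0)
})

test_that("world config YAML round trip preserves the simulation", {
  cfg <- tiny_world(seed = 19, n_mothers = 20)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_world_config(cfg, path)
  cfg2 <- read_world_config(path)
  expect_identical(simulate_fields(cfg)$pm_wfire,
                   simulate_fields(cfg2)$pm_wfire)
  expect_error(read_world_config({
    p <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(n_mothers = 5), p); p
  }), "rng_seed")
})
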