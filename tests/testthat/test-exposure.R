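test_that("fire fraction follows the with/without-fire differencing with clamping", {
  expect_equal(as.numeric(fire_fraction(60, 45)), 0.25)
  expect_equal(as.numeric(fire_fraction(10, 10)), 0)
  clamped <- fire_fraction(10, 12)
  expect_equal(as.numeric(clamped), 0)
  expect_identical(attr(clamped, "n_clamped"), 1L)
  expect_equal(as.numeric(fire_fraction(0, 0)), 0)   # zero with-fire rule
  expect_error(fire_fraction(-1, 5), "non-negative")
  # vectorised with a clamp count
  v <- fire_fraction(c(60, 10, 10), c(45, 12, 0))
  expect_equal(as.numeric(v), c(0.25, 0, 1))
  expect_identical(attr(v, "n_clamped"), 1L)
})

test_that("calibration rate is satellite over annual-mean with-fire", {
  expect_equal(calibration_rate(40, rep(50, 12)), 0.8)
  expect_equal(calibration_rate(33.3, rep(33.3, 12)), 1)
  expect_error(calibration_rate(40, rep(50, 11)), "12 monthly")
  expect_error(calibration_rate(40, rep(0, 12)), "undefined")
})

test_that("decomposition splits the calibrated total exactly", {
  d <- decompose_exposure(50, 0.25, 0.8)
  expect_equal(d, list(total = 40, fire = 10, nonfire = 30))
  expect_equal(decompose_exposure(50, 0, 0.8)$fire, 0)
  expect_equal(decompose_exposure(50, 0, 0.8)$nonfire, 40)
  expect_equal(decompose_exposure(50, 1, 0.8)$nonfire, 0)
  expect_error(decompose_exposure(50, 1.2, 0.8), "\\[0, 1\\]")
  expect_error(decompose_exposure(50, 0.5, 0), "positive")
  # conservation property over random inputs
  set.seed(1)
  w <- runif(500, 0, 200); r <- runif(500); e <- runif(500, 0.5, 1.5)
  d <- decompose_exposure(w, r, e)
  expect_lt(max(abs(d$fire + d$nonfire - d$total) / pmax(d$total, 1e-12)),
            1e-9)
})

test_that("IDW downscaling preserves constants, exact hits, and bounds", {
  lat <- c(0.5, 1.5, 2.5); lon <- c(0.5, 1.5, 2.5)
  const <- matrix(7, 3, 3)
  fine <- idw_downscale(const, lat, lon, seq(0.55, 2.45, 0.1),
                        seq(0.55, 2.45, 0.1))
  expect_equal(unname(fine), matrix(7, 20, 20), tolerance = 1e-12)

  z <- matrix(seq_len(9), 3, 3)
  hit <- idw_downscale(z, lat, lon, 1.5, 1.5)
  expect_equal(as.numeric(hit), z[2, 2])

  # query equidistant from 4 equal-distance neighbours with values 1,2,3,4:
  # the neighbours straddle the equator so great-circle symmetry is exact
  z2 <- matrix(c(1, 2, 3, 4), 2, 2)
  mid <- idw_downscale(z2, c(-0.5, 0.5), c(0.5, 1.5), 0, 1)
  expect_equal(as.numeric(mid), 2.5, tolerance = 1e-9)

  # convex combination: global bounds preserved
  set.seed(2)
  z3 <- matrix(runif(100, 3, 9), 10, 10)
  f3 <- idw_downscale(z3, seq(0.5, 9.5), seq(0.5, 9.5),
                      seq(0.05, 9.95, 0.1), seq(0.05, 9.95, 0.1))
  expect_gte(min(f3), min(z3) - 1e-12)
  expect_lte(max(f3), max(z3) + 1e-12)

  expect_error(idw_downscale(matrix(nrow = 0, ncol = 0), numeric(0),
                             numeric(0), 1, 1), "empty")
})

test_that("gestational-window means are inclusive and flag missing months", {
  months <- 1201:1212
  expect_equal(window_mean(rep(7, 12), months, 1203, 5), 7)
  expect_equal(window_mean(1:12, months, 1201, 4), 2.5)
  expect_equal(window_mean(1:12, months, 1205, 1), 5)
  expect_true(is.na(window_mean(1:12, months, 1210, 4)))   # runs off the end
  expect_true(is.na(window_mean(1:12, months, 1199, 3)))   # starts before
})

test_that("batched window means match the scalar rule and mark invalid events", {
  ids <- 1:3
  ser <- constant_series(ids, fire = 2)
  # give location 2 a ramp in fire so means are non-trivial
  ser$fire[2, ] <- seq_along(ser$months)
  wm <- window_means(ser, c(1, 2, 2), c(cmc(2000, 1), cmc(2000, 1), cmc(2014, 11)),
                     c(3, 4, 4), vars = "fire")
  expect_equal(wm$fire[1], 2)
  expect_equal(wm$fire[2], mean(1:4))
  expect_true(is.na(wm$fire[3]))     # window exceeds coverage
})
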