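test_that("case selection keeps each mother's most recent in-period loss", {
  ev <- rbind(event_row(1, "loss", cmc(2005, 2), 3),
              event_row(1, "loss", cmc(2010, 6), 4),
              event_row(1, "live_birth", cmc(2007, 1), 9),
              event_row(2, "loss", cmc(1998, 5), 4),      # out of period
              event_row(3, "loss", cmc(2012, 1), 2),
              event_row(3, "loss", cmc(2012, 4), 5))       # same termination month
  # mother 3: terminations 2012-02 and 2012-08 -> most recent is the second
  cases <- select_cases(ev, c(2000, 2014))
  expect_equal(sort(unique(cases$mother_id)), c(1, 3))
  expect_equal(cases$conception_cmc[cases$mother_id == 1], cmc(2010, 6))
  expect_equal(cases$conception_cmc[cases$mother_id == 3], cmc(2012, 4))
})

test_that("a tie in termination month is broken by input record order and reported", {
  ev <- rbind(event_row(5, "loss", cmc(2010, 1), 6),       # terminates 2010-06
              event_row(5, "loss", cmc(2010, 4), 3))       # also 2010-06
  cases <- select_cases(ev, c(2000, 2014))
  expect_equal(nrow(cases), 1L)
  expect_equal(cases$conception_cmc, cmc(2010, 1))         # first record wins
  expect_equal(attr(cases, "tied_mothers"), 5)
})

test_that("control windows take the case's gestation from the control's conception", {
  ev <- rbind(event_row(1, "loss", cmc(2010, 1), 4),
              event_row(1, "live_birth", cmc(2005, 3), 9),
              event_row(2, "loss", cmc(2010, 1), 4))        # no live birth
  ser <- constant_series(1:2)
  ser$fire[1, ] <- seq_along(ser$months)                    # ramp
  coh <- build_cohort(ev, ser, c(2000, 2014))
  expect_equal(length(unique(coh$set_id)), 1L)              # mother 2 dropped
  ctrl <- coh[coh$role == "control", ]
  expect_equal(ctrl$window_len, 4)                          # case gestation
  i0 <- match(cmc(2005, 3), ser$months)
  expect_equal(ctrl$fire, mean(seq(i0, i0 + 3)))            # [m, m+3]
  case <- coh[coh$role == "case", ]
  i1 <- match(cmc(2010, 1), ser$months)
  expect_equal(case$fire, mean(seq(i1, i1 + 3)))
  expect_equal(attr(coh, "n_dropped_no_control"), 1L)
})

test_that("controls with incomplete exposure windows are dropped", {
  ev <- rbind(event_row(1, "loss", cmc(2010, 1), 6),
              event_row(1, "live_birth", cmc(2014, 10), 9), # window runs off
              event_row(1, "live_birth", cmc(2006, 2), 9))
  ser <- constant_series(1)
  coh <- build_cohort(ev, ser, c(2000, 2014))
  expect_equal(sum(coh$role == "control"), 1L)
  expect_equal(coh$conception_cmc[coh$role == "control"], cmc(2006, 2))
})

test_that("subset flags implement the sensitivity definitions", {
  ev <- rbind(
    event_row(1, "loss", cmc(2010, 1), 5),                    # stillbirth case
    event_row(1, "live_birth", cmc(2006, 1), 9, singleton = FALSE,
              survival = 30, parity = 0),
    event_row(1, "live_birth", cmc(2012, 1), 9, singleton = TRUE,
              survival = 6, parity = 1),
    event_row(2, "loss", cmc(2010, 1), 3, parity = 0),        # miscarriage
    event_row(2, "live_birth", cmc(2012, 1), 9, parity = 0, survival = NA))
  ser <- constant_series(1:2, burned = 0, fire = 2)
  coh <- build_cohort(ev, ser, c(2000, 2014))
  c1 <- coh[coh$set_id == coh$set_id[coh$mother_id == 1][1], ]
  c2 <- coh[coh$set_id == coh$set_id[coh$mother_id == 2][1], ]

  expect_true(all(c1$flag_stillbirth) && !any(c1$flag_miscarriage))
  expect_true(all(c2$flag_miscarriage))
  # mother 1 has a non-singleton control and a control surviving < 12 months
  expect_false(any(c1$flag_singleton_controls))
  expect_false(any(c1$flag_surviving_controls))
  # unknown survival excludes under the surviving-infant flag only
  expect_false(any(c2$flag_surviving_controls))
  expect_true(all(c2$flag_singleton_controls))
  # bidirectional: controls both before and after the case termination
  expect_true(all(c1$flag_bidirectional))
  expect_false(any(c2$flag_bidirectional))
  # nulliparous pattern: all parity 0 and control after the case
  expect_true(all(c2$flag_parity_matched))
  expect_false(any(c1$flag_parity_matched))
  # burned area zero everywhere but fire PM2.5 positive -> transported fire
  expect_true(all(coh$flag_transported_fire))
  expect_true(all(coh$fire > 0))
})

test_that("recall flags compare whole months against 12 n", {
  survey <- cmc(2015, 6)
  ev <- rbind(event_row(1, "loss", cmc(2011, 1), 4, survey = survey),
              event_row(1, "live_birth", cmc(2008, 1), 9, survey = survey))
  ser <- constant_series(1)
  coh <- build_cohort(ev, ser, c(2000, 2014))
  # control termination 2008-09: recall 81 months; case 2011-04: 50 months
  expect_false(any(coh$flag_recall_6))   # 81 >= 72
  coh2 <- flag_subsets(coh, recall_years = c(7))
  expect_true(all(coh2$flag_recall_7))   # 81 < 84
})

test_that("subset restriction is monotone and window lengths stay matched", {
  cfg <- tiny_world(seed = 29, n_mothers = 600)
  f <- simulate_fields(cfg)
  ev <- simulate_mothers(cfg, f)
  mothers <- unique(ev[, c("mother_id", "lat", "lon")])
  ser <- extract_exposure(f, data.frame(id = mothers$mother_id,
                                        lat = mothers$lat, lon = mothers$lon))
  coh <- build_cohort(ev, ser)
  n_all <- length(unique(coh$set_id))
  for (s in c("miscarriage", "stillbirth", "singleton_controls",
              "surviving_controls", "parity_matched", "bidirectional",
              "transported_fire", "recall_5")) {
    sub <- subset_cohort(coh, s)
    n_sub <- length(unique(sub$set_id))
    expect_lte(n_sub, n_all)
    if (nrow(sub) > 0) {
      case_len <- tapply(sub$window_len[sub$role == "case"],
                         sub$set_id[sub$role == "case"], unique)
      all_len <- tapply(sub$window_len, sub$set_id, unique)
      expect_true(all(vapply(all_len, length, 1L) == 1L))
    }
  }
  # miscarriage and stillbirth partition the sets
  expect_equal(length(unique(subset_cohort(coh, "miscarriage")$set_id)) +
                 length(unique(subset_cohort(coh, "stillbirth")$set_id)),
               n_all)
  # every set has exactly one case; cases + controls = events analysed
  expect_equal(sum(coh$role == "case"), n_all)
  expect_equal(sum(coh$role == "case") + sum(coh$role == "control"),
               nrow(coh))
  expect_error(subset_cohort(coh, "no_such_flag"), "unknown subset")
})
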