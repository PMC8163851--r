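test_that("1:1 discordant pairs give the closed-form odds ratio exactly", {
  # 10 pairs with an exposed case only, 5 with an exposed control only:
  # conditional MLE for paired binary exposure is a/b = 2
  mk_pair <- function(id, case_x, ctrl_x)
    data.frame(set_id = id, role = c("case", "control"), x = c(case_x, ctrl_x))
  d <- do.call(rbind, c(lapply(1:10, mk_pair, case_x = 1, ctrl_x = 0),
                        lapply(11:15, mk_pair, case_x = 0, ctrl_x = 1)))
  fit <- fit_clogit(d, list(term_linear("x")))
  expect_equal(unname(exp(coef(fit)["x"])), 2, tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("Newton estimates match a dense grid search of the conditional likelihood", {
  set.seed(37)
  d <- conditional_sets(60, beta = c(0.6, -0.4), set_size = 2:3,
                        draw_x = function(n) cbind(x1 = rnorm(n),
                                                   x2 = rbinom(n, 1, 0.5)))
  fit <- fit_clogit(d, list(term_linear("x1"), term_linear("x2")))
  prep <- pyroloss:::prepare_sets(d)
  oracle <- clogit_grid_search(as.matrix(d[, c("x1", "x2")]), prep$set,
                               prep$case)
  expect_lt(max(abs(oracle$beta - unname(coef(fit)))), 1e-4)
  expect_gte(fit$loglik, oracle$loglik - 1e-8)
})

test_that("estimates agree with an independent conditional-logistic implementation", {
  skip_if_not_installed("survival")
  set.seed(41)
  d <- conditional_sets(400, beta = c(0.5, -0.3, 0.2), set_size = 2:4,
                        draw_x = function(n) cbind(x1 = rnorm(n),
                                                   x2 = runif(n),
                                                   x3 = rbinom(n, 1, 0.4)))
  fit <- fit_clogit(d, list(term_linear("x1"), term_linear("x2"),
                            term_linear("x3")))
  d$y <- d$role == "case"
  ref <- survival::coxph(survival::Surv(rep(1, nrow(d)), y) ~ x1 + x2 + x3 +
                           survival::strata(set_id),
                         data = d, method = "exact")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(ref))),
               tolerance = 1e-6)
  expect_equal(as.numeric(logLik(fit)), ref$loglik[2], tolerance = 1e-8)
})

test_that("set-constant covariates are cancelled without disturbing the rest", {
  set.seed(43)
  d <- conditional_sets(150, beta = 0.5, set_size = 3,
                        draw_x = function(n) cbind(x1 = rnorm(n)))
  d$z <- ave(rnorm(nrow(d)), d$set_id)        # constant within every set
  fit0 <- fit_clogit(d, list(term_linear("x1")))
  fit1 <- fit_clogit(d, list(term_linear("x1"), term_linear("z")))
  expect_true("z" %in% fit1$dropped)
  expect_true(is.na(coef(fit1)["z"]))
  expect_equal(coef(fit1)["x1"], coef(fit0)["x1"], tolerance = 1e-10)
  expect_equal(fit1$loglik, fit0$loglik, tolerance = 1e-10)
})

test_that("estimates are invariant to control order within sets", {
  set.seed(47)
  d <- conditional_sets(100, beta = 0.4, set_size = 4,
                        draw_x = function(n) cbind(x1 = rnorm(n)))
  fit_a <- fit_clogit(d, list(term_linear("x1")))
  perm <- unlist(lapply(split(seq_len(nrow(d)), d$set_id),
                        function(i) i[order(d$role[i] != "case",
                                            runif(length(i)))]))
  fit_b <- fit_clogit(d[perm, ], list(term_linear("x1")))
  expect_equal(coef(fit_a), coef(fit_b), tolerance = 1e-10)
})

test_that("sets without exactly one case are rejected", {
  d <- data.frame(set_id = c(1, 1, 2, 2), role = c("case", "case",
                                                   "control", "control"),
                  x = rnorm(4))
  expect_error(fit_clogit(d, list(term_linear("x"))), "exactly one case")
})

test_that("odds-ratio reporting respects the unit increment", {
  set.seed(53)
  d <- conditional_sets(300, beta = 0.05, set_size = 3,
                        draw_x = function(n) cbind(dm = rnorm(n, 20, 8)))
  fit <- fit_clogit(d, list(term_linear("dm", increment = 10)))
  r <- fit$or_table
  expect_equal(r$or, exp(10 * r$beta), tolerance = 1e-12)
  expect_lt(r$ci_low, r$or)
  expect_gt(r$ci_high, r$or)
})

test_that("likelihood-ratio test has the chi-square reference behaviour", {
  set.seed(59)
  d <- conditional_sets(200, beta = c(0.5, 0), set_size = 3,
                        draw_x = function(n) cbind(x1 = rnorm(n),
                                                   x2 = rnorm(n)))
  full <- fit_clogit(d, list(term_linear("x1"), term_linear("x2")))
  nested <- fit_clogit(d, list(term_linear("x1")))
  out <- lrt(nested, full)
  expect_equal(out$df, 1L)
  expect_gte(out$statistic, 0)
  # degenerate nesting: identical models
  same <- lrt(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # chi-square calibration at the textbook 5% critical value
  expect_equal(stats::pchisq(3.841459, 1, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)
  expect_error(lrt(full, nested), "fewer identifiable parameters")
})

test_that("parameter recovery and Wald coverage behave over replicates", {
  # moderate replicate study at small n; the acceptance suite runs the
  # full-size version
  set.seed(61)
  true_beta <- 0.5
  reps <- 60
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- conditional_sets(400, beta = true_beta, set_size = 3,
                          draw_x = function(n) cbind(x1 = rnorm(n)))
    f <- fit_clogit(d, list(term_linear("x1")))
    est[r] <- coef(f)["x1"]
    se[r] <- sqrt(vcov(f)["x1", "x1"])
  }
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - true_beta), 3 * mc_se)
  cover <- mean(abs(est - true_beta) <= 1.959964 * se)
  expect_gte(cover, 0.88)
  expect_lte(cover, 1.0)
})
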