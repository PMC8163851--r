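# Mother-stratified logistic simulation at the cohort level (no spatial
# fields): mothers with random intercepts and several pregnancies, loss drawn
# from the logistic model, case = most recent loss, controls = live births.
# Used for replicate studies of estimator bias and CI coverage.
stratified_cohort_sim <- function(n_mothers, beta_fire, beta_nonfire,
                                  alpha_mean = qlogis(0.18), alpha_sd = 1,
                                  n_preg_mean = 4) {
  n_preg <- pmax(stats::rpois(n_mothers, n_preg_mean - 1) + 1L, 2L)
  id <- rep.int(seq_len(n_mothers), n_preg)
  n_ev <- length(id)
  alpha <- stats::rnorm(n_mothers, alpha_mean, alpha_sd)
  fire <- stats::rlnorm(n_ev, 0, 0.8)          # right-skewed like fire PM2.5
  nonfire <- stats::rnorm(n_ev, 50, 8)
  lp <- alpha[id] + beta_fire * fire + beta_nonfire * (nonfire - 50)
  loss <- stats::runif(n_ev) < stats::plogis(lp)
  ord <- stats::ave(id, id, FUN = seq_along)   # pregnancy order = time order
  d <- data.frame(id = id, ord = ord, fire = fire, nonfire = nonfire,
                  loss = loss)
  # case: the mother's most recent loss; controls: all her live births
  last_loss <- stats::ave(ifelse(d$loss, d$ord, -1L), d$id, FUN = max)
  has_lb <- stats::ave(as.numeric(!d$loss), d$id, FUN = max) > 0.5
  keep <- last_loss > 0 & has_lb & (d$ord == last_loss | !d$loss)
  d <- d[keep, ]
  d$set_id <- match(d$id, unique(d$id))
  d$role <- ifelse(d$loss, "case", "control")
  d
}
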