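#' Conditional logistic regression for mother-matched sets
#'
#' Maximises the exact conditional likelihood of the matched case-control
#' design. With one case per set the contribution of set \eqn{s} is
#' \deqn{x_{case}\beta - \log \sum_{j \in s} \exp(x_j \beta)}
#' (no tie-handling variants arise). The score and observed information have
#' closed forms in the within-set softmax weights, and the fitter runs
#' Newton-Raphson with step-halving: a step that fails to increase the
#' log-likelihood is halved up to 10 times; convergence is a relative
#' log-likelihood change below 1e-10 within 50 iterations. Covariates that do
#' not vary within any set (or are collinear after within-set centering) are
#' cancelled by the conditioning; their coefficients are reported as `NA` and
#' flagged, and the remaining estimates equal those of the model omitting
#' them. The covariance is the inverse observed information; odds ratios and
#' Wald 95% intervals are reported per each term's unit increment.
#'
#' @param data analysis data with columns `set_id` and `role` (exactly one
#'   `"case"` per set), typically a [build_cohort()] result, possibly
#'   restricted via [subset_cohort()].
#' @param terms list of [term_spec] objects; exposure terms first by
#'   convention.
#' @param max_iter,tol Newton iteration cap and relative log-likelihood
#'   tolerance.
#' @return object of class `clogit_fit`: `coefficients` (NA where
#'   non-identifiable), `vcov`, `loglik`, `loglik_null`, `n_sets`,
#'   `n_events`, `iterations`, `converged`, `dropped` (non-identifiable
#'   column names), `or_table` (OR and 95% CI per unit increment for linear
#'   terms), plus the design metadata needed for prediction.
#' @examples
#' d <- data.frame(set_id = rep(1:3, each = 2),
#'                 role = rep(c("case", "control"), 3),
#'                 x = c(1, 0, 1, 0, 0, 1))
#' fit_clogit(d, list(term_linear("x")))
#' @export
fit_clogit <- function(data, terms, max_iter = 50L, tol = 1e-10) {
  prep <- prepare_sets(data)
  des <- build_design(data, terms)
  fit <- clogit_newton(des$X, prep$set, prep$case, max_iter, tol)
  finish_clogit(fit, des, prep, terms)
}

prepare_sets <- function(data) {
  if (!all(c("set_id", "role") %in% names(data)))
    stop("data must carry set_id and role columns")
  set <- match(data$set_id, unique(data$set_id))
  case <- data$role == "case"
  ncase <- tapply(case, set, sum)
  if (any(ncase != 1L))
    stop(sum(ncase != 1L), " sets do not have exactly one case")
  list(set = set, case = case, n_sets = max(set))
}

clogit_newton <- function(X, set, case, max_iter = 50L, tol = 1e-10) {
  n_sets <- max(set)
  if (nrow(X) != length(set)) stop("design/set length mismatch")

  # identifiability: within-set centering cancels set-constant columns
  keep <- identifiable_columns(X, set)
  Xk <- X[, keep, drop = FALSE]
  p <- ncol(Xk)
  ll_of <- function(beta) {
    eta <- drop(Xk %*% beta)
    mx <- tapply_max(eta, set, n_sets)
    lse <- mx + log(rowsum_vec(exp(eta - mx[set]), set, n_sets))
    sum(eta[case]) - sum(lse)
  }
  ll_null <- -sum(log(tabulate(set)))       # beta = 0
  beta <- rep(0, p)
  ll <- ll_null
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (p > 0L && iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(Xk %*% beta)
    mx <- tapply_max(eta, set, n_sets)
    e <- exp(eta - mx[set])
    denom <- rowsum_vec(e, set, n_sets)
    w <- e / denom[set]
    g <- drop(crossprod(Xk, case - w))
    S1 <- rowsum(Xk * w, set)
    info <- crossprod(Xk * sqrt(w)) - crossprod(S1)
    step <- tryCatch(solve(info, g), error = function(e)
      stop("singular information matrix; check for separation: ",
           conditionMessage(e)))
    ll_new <- ll_of(beta + step)
    halv <- 0L
    while ((!is.finite(ll_new) || ll_new < ll) && halv < 10L) {
      halv <- halv + 1L
      step <- step / 2
      ll_new <- ll_of(beta + step)
    }
    if (!is.finite(ll_new) || ll_new < ll) {
      # a Newton step that cannot improve beyond rounding noise means the
      # optimum is already reached; anything larger is a genuine failure
      if (is.finite(ll_new) && ll - ll_new < 1e-8 * (abs(ll) + 1)) {
        converged <- TRUE
        break
      }
      warning("step-halving failed to increase the conditional log-likelihood")
      break
    }
    beta <- beta + step
    done <- abs(ll_new - ll) < tol * (abs(ll) + tol)
    ll <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (p == 0L) converged <- TRUE
  vc <- if (p > 0L) {
    eta <- drop(Xk %*% beta)
    mx <- tapply_max(eta, set, n_sets)
    e <- exp(eta - mx[set])
    w <- e / rowsum_vec(e, set, n_sets)[set]
    S1 <- rowsum(Xk * w, set)
    solve(crossprod(Xk * sqrt(w)) - crossprod(S1))
  } else {
    matrix(numeric(0), 0, 0)
  }
  if (iter >= max_iter && !converged)
    stop("conditional logit failed to converge after ", max_iter,
         " iterations (last log-likelihood ", format(ll), ")")
  list(beta = beta, vcov = vc, keep = keep, loglik = ll,
       loglik_null = ll_null, iterations = iter, converged = converged,
       n_sets = n_sets, n_events = nrow(X))
}

identifiable_columns <- function(X, set) {
  ctr <- X - rowsum(X, set)[set, , drop = FALSE] / tabulate(set)[set]
  scale_ <- pmax(apply(abs(X), 2, max), 1)
  varying <- apply(abs(ctr), 2, max) / scale_ > 1e-10
  keep <- which(varying)
  if (length(keep) > 1L) {            # drop collinear columns (pivoted QR)
    qr_ <- qr(ctr[, keep, drop = FALSE])
    keep <- keep[sort(qr_$pivot[seq_len(qr_$rank)])]
  }
  keep
}

rowsum_vec <- function(x, g, n_g) {
  out <- rowsum(x, g)
  drop(out)[seq_len(n_g)]
}

tapply_max <- function(x, g, n_g) {
  out <- rep(-Inf, n_g)
  o <- order(g, x)
  out[g[o]] <- x[o]                    # last write per group is the max
  out
}

finish_clogit <- function(fit, des, prep, terms) {
  p_all <- ncol(des$X)
  beta <- rep(NA_real_, p_all)
  names(beta) <- colnames(des$X)
  beta[fit$keep] <- fit$beta
  vc <- matrix(NA_real_, p_all, p_all,
               dimnames = list(colnames(des$X), colnames(des$X)))
  vc[fit$keep, fit$keep] <- fit$vcov
  se <- sqrt(diag(vc))

  or_rows <- NULL
  for (nm in names(des$increments)) {
    if (!nm %in% names(beta)) next
    inc <- des$increments[[nm]]
    b <- beta[nm] * inc
    s <- se[nm] * inc
    or_rows <- rbind(or_rows, data.frame(
      term = nm, increment = inc, beta = beta[nm], se = se[nm],
      or = exp(b), ci_low = exp(b - 1.959964 * s),
      ci_high = exp(b + 1.959964 * s)))
  }
  structure(
    list(coefficients = beta, vcov = vc, loglik = fit$loglik,
         loglik_null = fit$loglik_null, n_sets = fit$n_sets,
         n_events = fit$n_events, iterations = fit$iterations,
         converged = fit$converged,
         dropped = setdiff(colnames(des$X), colnames(des$X)[fit$keep]),
         df = length(fit$keep), or_table = or_rows,
         term_of = des$term_of, bases = des$bases, terms = terms),
    class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("Conditional logistic fit: %d sets, %d events, logLik %.2f (%d iterations%s)\n",
              x$n_sets, x$n_events, x$loglik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  if (length(x$dropped))
    cat("  non-identifiable (set-constant/collinear):",
        paste(x$dropped, collapse = ", "), "\n")
  if (!is.null(x$or_table)) {
    cat("  odds ratios per unit increment:\n")
    for (r in seq_len(nrow(x$or_table)))
      with(x$or_table[r, ],
           cat(sprintf("    %-12s OR %.4f (95%% CI %.4f, %.4f) per %g\n",
                       term, or, ci_low, ci_high, increment)))
  }
  invisible(x)
}

#' @export
coef.clogit_fit <- function(object, ...) object$coefficients

#' @export
vcov.clogit_fit <- function(object, ...) object$vcov

#' @export
logLik.clogit_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

#' @export
confint.clogit_fit <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * se, object$coefficients + z * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Likelihood-ratio test between nested conditional-logit fits
#'
#' @param nested,full `clogit_fit`s on the same matched sets; the nested
#'   model's identifiable parameter count must not exceed the full model's.
#' @return list with `statistic`, `df`, `p_value`.
#' @examples
#' # identical models give statistic 0, p = 1
#' @export
lrt <- function(nested, full) {
  if (nested$n_sets != full$n_sets || nested$n_events != full$n_events)
    stop("models were fitted on different data")
  df <- full$df - nested$df
  if (df < 0)
    stop("the 'full' model has fewer identifiable parameters than the nested one")
  stat <- max(0, 2 * (full$loglik - nested$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}
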