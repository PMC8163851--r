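#' Exposure-by-subgroup interaction analysis
#'
#' Tests whether the exposure association differs between population
#' subgroups (maternal age group, education, residence, ...). The subgroup
#' indicator is defined at the case level and shared by the whole set, so its
#' main effect is cancelled by the conditioning; it enters only through the
#' interaction: the single exposure slope is replaced by one slope per
#' subgroup. Heterogeneity is judged by a likelihood-ratio test of this model
#' against the common-slope model.
#'
#' @param data matched analysis data (see [fit_clogit()]).
#' @param terms adjustment [term_spec] list (must not already contain the
#'   exposure).
#' @param group_var column holding the subgroup label; if it varies within a
#'   set, the case's value defines the set's group under
#'   `define_by = "case"`.
#' @param exposure exposure column name.
#' @param increment unit increment for subgroup OR reporting.
#' @param define_by `"case"` (default) assigns every event the case's
#'   subgroup — appropriate for mother-level indicators such as education.
#'   `"event"` lets each event carry its own value — appropriate for
#'   covariates that evolve across a mother's pregnancies, such as maternal
#'   age, where susceptibility belongs to the pregnancy rather than the
#'   mother.
#' @return list with `by_group` (data.frame: group, n_sets, beta, se, OR and
#'   CI per increment), `heterogeneity` (LRT statistic, df, p), and the two
#'   underlying fits `fit_interaction`, `fit_common`.
#' @export
fit_subgroup_interaction <- function(data, terms, group_var,
                                     exposure = "fire", increment = 1,
                                     define_by = c("case", "event")) {
  define_by <- match.arg(define_by)
  if (!group_var %in% names(data)) stop("no such column: ", group_var)
  is_case <- data$role == "case"
  if (define_by == "case") {
    v <- ifelse(is_case, as.character(data[[group_var]]), NA)
    set_grp <- stats::ave(v, data$set_id,
                          FUN = function(z) z[!is.na(z)][1])
  } else {
    set_grp <- as.character(data[[group_var]])
  }
  lev <- sort(unique(set_grp))
  if (length(lev) < 2L)
    stop("subgroup heterogeneity is undefined with a single group (",
         lev, ")")
  d <- as.data.frame(data)
  for (g in lev)
    d[[paste0(".x_", g)]] <- d[[exposure]] * (set_grp == g)

  int_terms <- c(lapply(lev, function(g)
    term_linear(paste0(".x_", g), increment = increment,
                label = paste0(exposure, "[", g, "]"))), terms)
  common_terms <- c(list(term_linear(exposure, increment = increment)), terms)

  fit_int <- fit_clogit(d, int_terms)
  fit_common <- fit_clogit(d, common_terms)
  het <- lrt(fit_common, fit_int)

  ot <- fit_int$or_table
  by_group <- ot[match(paste0(exposure, "[", lev, "]"), ot$term), ]
  by_group$group <- lev
  cases <- d[is_case, ]
  by_group$n_sets <- as.integer(table(set_grp[is_case])[lev])
  rownames(by_group) <- NULL
  by_group <- by_group[, c("group", "n_sets", "beta", "se", "increment",
                           "or", "ci_low", "ci_high")]
  list(by_group = by_group, heterogeneity = het,
       fit_interaction = fit_int, fit_common = fit_common)
}
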