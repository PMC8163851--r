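#' Select pregnancy-loss cases
#'
#' One case per mother: among her losses whose termination falls inside the
#' study period, the most recent one (gestational details are recalled, so
#' recency limits recall error). Two losses terminating in the same month are
#' tied; the tie is broken deterministically by input record order (first
#' record wins) and the affected mothers are reported in an attribute.
#'
#' @param events pregnancy-event data.frame (see [simulate_mothers()] /
#'   [read_events_csv()]).
#' @param study_period `c(first, last)` calendar years of eligible
#'   terminations.
#' @return the case rows, one per retained mother, with attribute
#'   `"tied_mothers"`.
#' @export
select_cases <- function(events, study_period) {
  lo <- cmc(study_period[1], 1)
  hi <- cmc(study_period[2], 12)
  losses <- events[events$outcome == "loss" &
                     events$termination_cmc >= lo &
                     events$termination_cmc <= hi, , drop = FALSE]
  if (nrow(losses) == 0L) {
    out <- losses
    attr(out, "tied_mothers") <- integer(0)
    return(out)
  }
  losses$.row <- seq_len(nrow(losses))
  best <- stats::ave(losses$termination_cmc, losses$mother_id, FUN = max)
  recent <- losses[losses$termination_cmc == best, , drop = FALSE]
  dup <- duplicated(recent$mother_id)
  tied <- unique(recent$mother_id[dup])
  out <- recent[!dup, , drop = FALSE]     # first input record wins a tie
  out$.row <- NULL
  attr(out, "tied_mothers") <- tied
  out
}

#' Build the mother-matched case-control cohort
#'
#' Constructs one matched set per retained mother: her selected loss (case)
#' plus every live birth (control) with valid exposure over a window starting
#' at the control's own conception and lasting the case's gestation length —
#' the exposure-time-window matching of the self-comparison design. Sets
#' whose case has invalid exposure or with zero valid controls are dropped.
#' Every environmental covariate is averaged over the event's matched window;
#' maternal age, conception month, and conception year are event-specific,
#' so they vary within sets and remain identifiable under conditioning.
#' Sensitivity-subset eligibility flags are attached per set (see
#' [flag_subsets()]).
#'
#' @param events pregnancy-event data.frame.
#' @param series [extract_exposure()] result covering the mothers' locations
#'   (`series$ids` must contain every `mother_id`).
#' @param study_period `c(first, last)` calendar years for case selection.
#' @param recall_years recall-period thresholds (years) to flag.
#' @return a `matched_cohort`: long data.frame, one row per event, columns
#'   `set_id`, `role` ("case"/"control"), the event fields, window means
#'   (`fire`, `nonfire`, `total`, `temperature`, `humidity`, `burned_frac`,
#'   `dry_matter`), `window_len`, derived covariates (`age_band`,
#'   `age_group`, `conc_month`, `conc_year`), and set-level logical flag
#'   columns (`flag_*`). Attributes record counts of dropped cases.
#' @export
build_cohort <- function(events, series, study_period = NULL,
                         recall_years = c(3, 4, 5, 6)) {
  if (is.null(study_period)) {
    study_period <- range(cmc_year(series$months))
  }
  cases <- select_cases(events, study_period)
  if (nrow(cases) == 0L) stop("no eligible cases in the study period")

  loc_row <- match(cases$mother_id, series$ids)
  if (anyNA(loc_row)) stop("exposure series missing some mothers")
  vars <- c("fire", "nonfire", "total", "temperature", "humidity",
            "burned_frac", "dry_matter")
  wm_case <- window_means(series, loc_row, cases$conception_cmc,
                          cases$gestation_months, vars)
  case_valid <- !is.na(wm_case$fire)

  controls <- events[events$outcome == "live_birth" &
                       events$mother_id %in% cases$mother_id, , drop = FALSE]
  cmatch <- match(controls$mother_id, cases$mother_id)
  ctrl_window <- cases$gestation_months[cmatch]
  wm_ctrl <- window_means(series, match(controls$mother_id, series$ids),
                          controls$conception_cmc, ctrl_window, vars)
  ctrl_valid <- !is.na(wm_ctrl$fire)

  n_ctrl <- tapply(ctrl_valid, factor(controls$mother_id,
                                      levels = cases$mother_id), sum)
  n_ctrl[is.na(n_ctrl)] <- 0L
  keep_case <- case_valid & n_ctrl > 0
  kept <- cases$mother_id[keep_case]

  case_rows <- cbind(cases[keep_case, , drop = FALSE],
                     wm_case[keep_case, , drop = FALSE])
  case_rows$role <- "case"
  case_rows$window_len <- case_rows$gestation_months
  kc <- ctrl_valid & controls$mother_id %in% kept
  ctrl_rows <- cbind(controls[kc, , drop = FALSE], wm_ctrl[kc, , drop = FALSE])
  ctrl_rows$role <- "control"
  ctrl_rows$window_len <- ctrl_window[kc]

  cohort <- rbind(case_rows, ctrl_rows)
  cohort$set_id <- match(cohort$mother_id, kept)
  cohort <- cohort[order(cohort$set_id, cohort$role == "control",
                         cohort$conception_cmc), , drop = FALSE]
  rownames(cohort) <- NULL

  cohort$age_band <- age_band_label(age_band(cohort$maternal_age_years))
  cohort$age_group <- age_group3(cohort$maternal_age_years)
  cohort$conc_month <- cmc_month(cohort$conception_cmc)
  cohort$conc_year <- cmc_year(cohort$conception_cmc)

  cohort <- flag_subsets(cohort, recall_years = recall_years)
  structure(cohort,
            class = c("matched_cohort", "data.frame"),
            n_cases_period = nrow(cases),
            n_dropped_invalid_case = sum(!case_valid),
            n_dropped_no_control = sum(case_valid & n_ctrl == 0),
            tied_mothers = attr(cases, "tied_mothers"))
}

#' Sensitivity-subset eligibility flags
#'
#' Attaches per-set logical flags used by the sensitivity analyses:
#' \describe{
#'   \item{flag_miscarriage / flag_stillbirth}{case gestation <5 months
#'     (miscarriage) or >=5 months (stillbirth).}
#'   \item{flag_singleton_controls}{every control is a singleton birth.}
#'   \item{flag_surviving_controls}{every control survived more than 12
#'     months with known status.}
#'   \item{flag_parity_matched}{case and controls all nulliparous with every
#'     control after the case, or all multiparous.}
#'   \item{flag_bidirectional}{at least one control terminates before and at
#'     least one after the case's termination.}
#'   \item{flag_transported_fire}{zero burned-area fraction in every month of
#'     every window in the set (smoke without local burning).}
#'   \item{flag_recall_N}{survey-to-termination recall under N years
#'     (in whole months, < 12 N) for the case and every control.}
#' }
#' Flags are set-level: every row of a set carries the same values.
#'
#' @param cohort a `matched_cohort` (or its data.frame).
#' @param recall_years recall thresholds in years.
#' @return the cohort with `flag_*` columns added or refreshed.
#' @export
flag_subsets <- function(cohort, recall_years = c(3, 4, 5, 6)) {
  sid <- cohort$set_id
  is_case <- cohort$role == "case"
  # optional survey columns may be absent in user-prepared extracts; an
  # absent or NA value fails the flags that depend on it, nothing else
  for (col in c("singleton", "infant_survival_months", "parity_before"))
    if (!col %in% names(cohort)) cohort[[col]] <- NA
  set_all <- function(x) {
    v <- stats::ave(as.numeric(x %in% TRUE), sid, FUN = min) > 0.5
    v %in% TRUE
  }
  set_any <- function(x) {
    v <- stats::ave(as.numeric(x %in% TRUE), sid, FUN = max) > 0.5
    v %in% TRUE
  }
  from_case <- function(x) {       # broadcast the case's value over its set
    v <- x
    v[!is_case] <- NA
    stats::ave(v, sid, FUN = function(z) z[!is.na(z)][1])
  }

  case_gest <- from_case(cohort$gestation_months)
  cohort$flag_miscarriage <- case_gest < 5
  cohort$flag_stillbirth <- case_gest >= 5

  single_ok <- is_case | (cohort$singleton %in% TRUE)
  cohort$flag_singleton_controls <- set_all(single_ok)
  surv_ok <- is_case |
    (!is.na(cohort$infant_survival_months) & cohort$infant_survival_months > 12)
  cohort$flag_surviving_controls <- set_all(surv_ok)

  case_term <- from_case(cohort$termination_cmc)
  nulli <- set_all(cohort$parity_before == 0) &
    set_all(is_case | cohort$termination_cmc > case_term)
  multi <- set_all(cohort$parity_before >= 1)
  cohort$flag_parity_matched <- nulli | multi

  cohort$flag_bidirectional <-
    set_any(!is_case & cohort$termination_cmc < case_term) &
    set_any(!is_case & cohort$termination_cmc > case_term)

  # burned_frac >= 0, so a zero window mean means zero in every window month
  cohort$flag_transported_fire <- set_all(cohort$burned_frac == 0)

  for (n in recall_years) {
    cohort[[paste0("flag_recall_", n)]] <-
      set_all(cohort$survey_cmc - cohort$termination_cmc < 12 * n)
  }
  cohort
}

#' Restrict a matched cohort to a sensitivity subset
#'
#' @param cohort a `matched_cohort`.
#' @param subset name of a flag without the `flag_` prefix (e.g.
#'   `"miscarriage"`, `"bidirectional"`, `"recall_4"`).
#' @return the cohort restricted to flagged sets (attributes preserved).
#' @export
subset_cohort <- function(cohort, subset) {
  col <- paste0("flag_", subset)
  if (!col %in% names(cohort))
    stop("unknown subset flag: ", subset, "; available: ",
         paste(sub("^flag_", "", grep("^flag_", names(cohort), value = TRUE)),
               collapse = ", "))
  out <- cohort[cohort[[col]], , drop = FALSE]
  class(out) <- class(cohort)
  out
}

#' @export
print.matched_cohort <- function(x, ...) {
  n_sets <- length(unique(x$set_id))
  cat(sprintf("Matched cohort: %d sets, %d events (%d cases, %d controls)\n",
              n_sets, nrow(x), sum(x$role == "case"),
              sum(x$role == "control")))
  fl <- grep("^flag_", names(x), value = TRUE)
  if (length(fl)) {
    cs <- x[x$role == "case", fl, drop = FALSE]
    cat("  eligible sets per subset:\n")
    for (f in fl)
      cat(sprintf("    %-22s %d\n", sub("^flag_", "", f), sum(cs[[f]])))
  }
  invisible(x)
}

#' Long-format matched-set export
#'
#' @param cohort a `matched_cohort`.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
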