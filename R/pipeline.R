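#' Run the full analysis pipeline
#'
#' Orchestrates the stages simulate -> exposure -> cohort -> fit -> impact
#' from a single declarative configuration and writes their outputs plus a
#' machine-readable run manifest. The fit stage covers the main fully
#' adjusted, mutually adjusted model, the four covariate/mutual adjustment
#' combinations, the sensitivity subsets, the subgroup interaction models,
#' and the nonlinear exposure-response. All randomness flows from a single
#' root seed split per stage, so one config and seed reproduce one result.
#'
#' @param config run configuration: a list (or YAML path for
#'   [read_run_config()]) with elements
#'   \describe{
#'     \item{seed}{root seed (mandatory unless the world config carries one).}
#'     \item{world}{[world_config()] argument overrides for simulation, or}
#'     \item{fields_nc, events_csv}{paths to pre-existing inputs instead of
#'       simulating.}
#'     \item{out_dir}{output directory (created).}
#'     \item{stages}{named logicals: `simulate`, `exposure`, `cohort`,
#'       `fit`, `impact`; a disabled later stage stops the run early.}
#'     \item{study_period}{`c(first, last)` years for case selection.}
#'     \item{subsets}{sensitivity-subset flags to refit (character).}
#'     \item{subgroups}{subgroup columns for interaction models.}
#'     \item{nonlinear_df}{spline df for the exposure-response (0 skips).}
#'     \item{write_fields_nc, write_exposure_csv}{heavyweight output
#'       toggles, default off.}
#'   }
#' @return the run manifest (invisibly also written as `manifest.json`):
#'   seed, versions, per-stage row counts, input hashes, and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- stage_toggles(config$stages)
  out_dir <- config$out_dir %||% "pyroloss-run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[pyroloss] ", sprintf(...))
  manifest <- list(package = "pyroloss",
                   version = as.character(utils::packageVersion("pyroloss")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   stages = stages, counts = list(), inputs = list(),
                   outputs = list())

  # ---- inputs: simulate or load -------------------------------------------
  if (!is.null(config$fields_nc)) {
    if (!file.exists(config$fields_nc))
      stop("fields_nc does not exist: ", config$fields_nc)
    if (!is.null(config$events_csv) && !file.exists(config$events_csv))
      stop("events_csv does not exist: ", config$events_csv)
    log_msg("loading fields from %s", config$fields_nc)
    fields <- read_fields_nc(config$fields_nc)
    events <- read_events_csv(config$events_csv)
    manifest$inputs$fields_nc <- unname(tools::md5sum(config$fields_nc))
    manifest$inputs$events_csv <- unname(tools::md5sum(config$events_csv))
    seed <- config$seed %||% fields$config$rng_seed
  } else {
    wargs <- config$world %||% list()
    if (!is.null(config$seed)) wargs$rng_seed <- config$seed
    wcfg <- do.call(world_config, wargs)
    seed <- wcfg$rng_seed
    if (!stages$simulate) stop("no input paths given and simulate stage disabled")
    log_msg("simulating fields (seed %d)", seed)
    fields <- simulate_fields(wcfg)
    log_msg("simulating %d mothers", wcfg$n_mothers)
    events <- simulate_mothers(wcfg, fields)
    if (isTRUE(config$write_fields_nc)) {
      p <- file.path(out_dir, "fields.nc")
      write_fields_nc(fields, p)
      manifest$outputs$fields_nc <- p
    }
    p <- file.path(out_dir, "events.csv")
    write_events_csv(events, p)
    manifest$outputs$events_csv <- p
  }
  manifest$seed <- seed
  manifest$counts$events <- nrow(events)
  manifest$counts$mothers <- length(unique(events$mother_id))
  if (!stages$exposure) return(finish_manifest(manifest, out_dir))

  # ---- exposure -----------------------------------------------------------
  log_msg("extracting calibrated exposure series")
  mothers <- unique(events[, c("mother_id", "lat", "lon")])
  series <- extract_exposure(fields, data.frame(
    id = mothers$mother_id, lat = mothers$lat, lon = mothers$lon))
  if (isTRUE(config$write_exposure_csv)) {
    p <- file.path(out_dir, "exposure.csv")
    write_exposure_csv(series, p)
    manifest$outputs$exposure_csv <- p
  }
  if (!stages$cohort) return(finish_manifest(manifest, out_dir))

  # ---- cohort -------------------------------------------------------------
  period <- config$study_period %||% range(cmc_year(series$months))
  log_msg("building matched cohort (period %d-%d)", period[1], period[2])
  cohort <- build_cohort(events, series, study_period = period)
  p <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(cohort, p)
  manifest$outputs$cohort_csv <- p
  n_sets <- length(unique(cohort$set_id))
  manifest$counts$matched_sets <- n_sets
  manifest$counts$cases <- sum(cohort$role == "case")
  manifest$counts$controls <- sum(cohort$role == "control")
  manifest$counts$events_analysed <- nrow(cohort)
  if (!stages$fit) return(finish_manifest(manifest, out_dir))

  # ---- fits ---------------------------------------------------------------
  adj <- adjustment_terms()
  exp_fire <- list(term_linear("fire"))
  exp_both <- list(term_linear("fire"), term_linear("nonfire"))
  log_msg("fitting main model (%d sets)", n_sets)
  main_fit <- fit_clogit(cohort, c(exp_both, adj))
  write_fit_csv(main_fit, file.path(out_dir, "fit_main.csv"),
                file.path(out_dir, "fit_main.json"))
  manifest$outputs$fit_main <- file.path(out_dir, "fit_main.csv")
  manifest$counts$fit_main_df <- main_fit$df

  combos <- list(
    crude = exp_fire,
    crude_mutual = exp_both,
    adjusted = c(exp_fire, adj),
    adjusted_mutual = c(exp_both, adj))
  tab <- NULL
  for (nm in names(combos)) {
    f <- if (nm == "adjusted_mutual") main_fit else fit_clogit(cohort, combos[[nm]])
    r <- f$or_table[f$or_table$term == "fire", ]
    tab <- rbind(tab, cbind(model = nm, r))
  }
  utils::write.csv(tab, file.path(out_dir, "fit_adjustment_combos.csv"),
                   row.names = FALSE)
  manifest$outputs$adjustment_combos <- file.path(out_dir, "fit_adjustment_combos.csv")

  subsets <- config$subsets %||%
    c("miscarriage", "stillbirth", "singleton_controls",
      "surviving_controls", "parity_matched", "bidirectional",
      "transported_fire", "recall_3", "recall_4", "recall_5", "recall_6")
  sub_tab <- NULL
  for (s in subsets) {
    d <- subset_cohort(cohort, s)
    ns <- length(unique(d$set_id))
    if (ns < 50) { log_msg("subset %s: only %d sets, skipped", s, ns); next }
    f <- tryCatch(fit_clogit(d, c(exp_both, adj)), error = function(e) NULL)
    if (is.null(f)) { log_msg("subset %s: fit failed", s); next }
    r <- f$or_table[f$or_table$term == "fire", ]
    sub_tab <- rbind(sub_tab, cbind(subset = s, n_sets = ns, r))
  }
  if (!is.null(sub_tab)) {
    utils::write.csv(sub_tab, file.path(out_dir, "fit_subsets.csv"),
                     row.names = FALSE)
    manifest$outputs$subsets <- file.path(out_dir, "fit_subsets.csv")
  }

  subgroups <- config$subgroups %||% c("age_group", "education", "residence")
  grp_tab <- NULL
  for (g in subgroups) {
    res <- tryCatch(
      fit_subgroup_interaction(cohort, adj, g,
                               define_by = if (g == "age_group") "event"
                                           else "case"),
      error = function(e) NULL)
    if (is.null(res)) next
    bg <- res$by_group
    bg$heterogeneity_p <- res$heterogeneity$p_value
    grp_tab <- rbind(grp_tab, cbind(variable = g, bg))
  }
  if (!is.null(grp_tab)) {
    utils::write.csv(grp_tab, file.path(out_dir, "fit_subgroups.csv"),
                     row.names = FALSE)
    manifest$outputs$subgroups <- file.path(out_dir, "fit_subgroups.csv")
  }

  nl_df <- config$nonlinear_df %||% 3
  if (nl_df >= 2) {
    nl <- fit_nonlinear_exposure(cohort, adj, df = nl_df)
    curve <- nl$curve
    curve$linearity_p <- nl$linearity_test$p_value
    utils::write.csv(curve, file.path(out_dir, "exposure_response.csv"),
                     row.names = FALSE)
    manifest$outputs$exposure_response <- file.path(out_dir, "exposure_response.csv")
  }
  if (!stages$impact) return(finish_manifest(manifest, out_dir))

  # ---- impact -------------------------------------------------------------
  log_msg("attributable-fraction accounting")
  imp <- impact_summary(main_fit, cohort)
  utils::write.csv(imp, file.path(out_dir, "impact.csv"), row.names = FALSE)
  cmpz <- attr(imp, "comparison")
  jsonlite::write_json(
    list(fire_share = cmpz$fire_share,
         excess_risk_ratio_pct = cmpz$excess_risk_ratio_pct),
    file.path(out_dir, "impact.json"), auto_unbox = TRUE, digits = NA)
  manifest$outputs$impact <- file.path(out_dir, "impact.csv")
  finish_manifest(manifest, out_dir)
}

stage_toggles <- function(x) {
  def <- list(simulate = TRUE, exposure = TRUE, cohort = TRUE,
              fit = TRUE, impact = TRUE)
  for (nm in names(x)) {
    if (!nm %in% names(def)) stop("unknown stage: ", nm)
    def[[nm]] <- isTRUE(x[[nm]])
  }
  def
}

finish_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param path YAML run-configuration file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (f in c("study_period"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  cfg
}

write_fit_csv <- function(fit, csv_path, json_path = NULL) {
  co <- data.frame(coef = names(fit$coefficients),
                   term = fit$term_of,
                   estimate = unname(fit$coefficients),
                   se = sqrt(diag(fit$vcov)))
  utils::write.csv(co, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(loglik = fit$loglik, loglik_null = fit$loglik_null,
           df = fit$df, n_sets = fit$n_sets, n_events = fit$n_events,
           iterations = fit$iterations, converged = fit$converged,
           dropped = fit$dropped,
           or_table = fit$or_table),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
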