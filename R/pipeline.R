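# Orchestration: simulate -> cohorts -> episodes -> weights -> Cox/KM ->
# subgroups -> sensitivity, as one reproducible run writing CSV artifacts
# plus a manifest.

#' Run configuration
#'
#' Bundles every tunable of a pipeline run. The configuration (and the
#' seed) is serialized into the output directory so a run is reproducible
#' from its artifacts alone.
#'
#' @param seed Integer seed (also forwarded to the simulator).
#' @param sim A [sim_config()] (used when the pipeline simulates its input).
#' @param rules An [eligibility_rules()].
#' @param opts An [episode_options()].
#' @param subgroups Baseline columns for subgroup/interaction analysis.
#' @param horizons Sensitivity horizons in days (5-year grid = 1,800;
#'   10-year = 3,780).
#' @param truncation_percentiles Optional weight-truncation probabilities.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       sim = sim_config(seed = seed),
                       rules = eligibility_rules(),
                       opts = episode_options(),
                       subgroups = c("sex", "diabetes0"),
                       horizons = c(1800L, 3780L),
                       truncation_percentiles = NULL) {
  structure(list(seed = as.integer(seed), sim = sim, rules = rules,
                 opts = opts, subgroups = subgroups,
                 horizons = as.integer(horizons),
                 truncation_percentiles = truncation_percentiles),
            class = "run_config")
}

#' Serialize / load a run configuration
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` the path invisibly; `read_run_config` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  listify <- function(x) {
    if (inherits(x, "Date")) return(format(x, "%Y-%m-%d"))
    if (is.list(x)) return(lapply(x, listify))
    if (!is.null(names(x)) && length(x) > 1L) return(as.list(x))
    x
  }
  yaml::write_yaml(listify(unclass(config)), path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(seed = raw$seed)
  for (nm in intersect(names(raw$rules), names(cfg$rules)))
    cfg$rules[[nm]] <- raw$rules[[nm]]
  for (nm in intersect(names(raw$opts), names(cfg$opts)))
    cfg$opts[[nm]] <- raw$opts[[nm]]
  sim_args <- raw$sim
  if (!is.null(sim_args)) {
    sim_args$study_start <- as.Date(sim_args$study_start)
    sim_args$study_end <- as.Date(sim_args$study_end)
    for (nm in c("true_log_hr", "confounder_hazard", "comorbidity_baseline",
                 "comorbidity_onset"))
      sim_args[[nm]] <- unlist(sim_args[[nm]])
    sim_args$class_assignment <- lapply(sim_args$class_assignment, unlist)
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg$subgroups <- raw$subgroups
  cfg$horizons <- as.integer(raw$horizons)
  cfg
}

analyse_cohort <- function(members, summaries, pp_all, db, model,
                           subgroups, horizons, truncation = NULL) {
  pp <- pp_all[patient_id %in% members$patient_id]
  bl <- baseline_covariates(members, db, pp, summaries)
  ppc <- attach_baseline_covariates(pp, bl)
  spec <- weight_model_spec(model, truncation_percentiles = truncation)
  models <- fit_propensity_models(ppc, spec)
  w <- compute_stabilized_weights(ppc, models)
  crude <- fit_cox(ppc)
  weighted <- fit_cox(ppc, weights = w$sw_baseline)
  km <- rbind(cbind(weighted = FALSE, estimate_km(ppc)),
              cbind(weighted = TRUE, estimate_km(ppc, weights = w$sw_baseline)))
  pps <- attach_subgroup_columns(ppc, bl, subgroups)
  sub <- rbindlist(lapply(intersect(subgroups, names(pps)), function(v)
    run_subgroups(pps, weights = w$sw_baseline, variable = v)))
  inter <- rbindlist(lapply(intersect(subgroups, names(pps)), function(v) {
    res <- tryCatch(
      suppressWarnings(test_interaction(pps, weights = w$sw_baseline,
                                        variable = v)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    cbind(data.table(subgroup_variable = v), res$overall)
  }))
  sens <- rbindlist(lapply(horizons, function(h) {
    st <- truncate_followup(summaries[patient_id %in% members$patient_id], h)
    ppt <- build_person_periods_from_truncation(ppc, st)
    wt <- w[ppt[, .(patient_id, k)], on = c("patient_id", "k")]
    rbind(cbind(horizon_days = h, fit_cox(ppt)),
          cbind(horizon_days = h, fit_cox(ppt, weights = wt$sw_baseline)))
  }))
  list(baseline = summarize_baseline(bl), weights = w, crude = crude,
       weighted = weighted, km = km, subgroups = sub, interactions = inter,
       sensitivity = sens, events = summarize_events(members, summaries),
       pp = ppc, members = members)
}

attach_subgroup_columns <- function(pp, bl, subgroups) {
  extra <- setdiff(intersect(subgroups, names(bl)), names(pp))
  if (length(extra)) {
    pp <- copy(pp)
    pp[bl, (extra) := mget(paste0("i.", extra)), on = "patient_id"]
  }
  pp
}

# Truncate existing person-period rows to re-derived summaries: rows fully
# before the truncated end survive unchanged; the terminal row is clipped.
build_person_periods_from_truncation <- function(pp, summaries) {
  out <- pp[summaries[, .(patient_id, fu_new = followup_days,
                          ev_new = event)],
            on = "patient_id", nomatch = NULL]
  out <- out[start_day < fu_new]
  out[, stop_day := pmin(stop_day, fu_new)]
  out[, event := ev_new & stop_day == fu_new]
  out[, c("fu_new", "ev_new") := NULL]
  out[]
}

#' Run the full pipeline on a simulated database
#'
#' Simulates a prescription database from `config$sim`, builds cohorts 1
#' and 2, derives person-periods, fits Model-1 weights in cohort 1 and
#' Model-2 weights in cohort 2, and produces crude and weighted hazard
#' ratios, Kaplan-Meier curves, subgroup and interaction results,
#' sensitivity-cohort tables, the baseline table, an attrition flow, and a
#' planted-vs-estimated comparison. If `out_dir` is given, every table is
#' written as CSV together with the serialized configuration and a manifest
#' (stage, rows, md5, wall time).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory.
#' @param db Optional `rx_db` to analyse instead of simulating (truth
#'   tables are then omitted).
#' @return List of stage results (invisible when writing to `out_dir`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, db = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    stages[[stage]] <<- t1 - tick_prev
    tick_prev <<- t1
  }
  tick_prev <- t0

  truth <- NULL
  if (is.null(db)) {
    sim <- simulate_population(config$sim)
    db <- sim$db
    truth <- sim$truth
  }
  tick("simulate")
  cohorts <- build_cohorts(db, config$rules, config$opts)
  tick("cohorts")
  pp_all <- build_person_periods(db, cohorts$summaries, config$opts)
  tick("episodes")
  res1 <- analyse_cohort(cohorts$cohort1, cohorts$summaries, pp_all, db,
                         model = 1L, config$subgroups, config$horizons,
                         config$truncation_percentiles)
  tick("analyse_cohort1")
  res2 <- analyse_cohort(cohorts$cohort2, cohorts$summaries, pp_all, db,
                         model = 2L, config$subgroups, config$horizons,
                         config$truncation_percentiles)
  tick("analyse_cohort2")

  planted <- NULL
  if (!is.null(truth)) {
    est <- rbind(cbind(cohort = 1L, res1$crude, model = "crude"),
                 cbind(cohort = 1L, res1$weighted, model = "iptw"),
                 cbind(cohort = 2L, res2$crude, model = "crude"),
                 cbind(cohort = 2L, res2$weighted, model = "iptw"))
    est[, exposure_class := sub(" vs BB$", "", comparison)]
    planted <- merge(est,
                     data.table(exposure_class = names(truth$true_hr),
                                true_hr = unname(truth$true_hr)),
                     by = "exposure_class")
  }
  out <- list(db = db, truth = truth, cohorts = cohorts,
              person_periods = pp_all, cohort1 = res1, cohort2 = res2,
              planted_vs_estimated = planted, stage_seconds = stages)
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write_rx_db(out$db, file.path(out_dir, "db"))
  files <- list(
    "attrition.csv" = out$cohorts$attrition,
    "decisions.csv" = out$cohorts$decisions,
    "followup_summaries.csv" = out$cohorts$summaries,
    "person_periods.csv" = out$person_periods,
    "cohort1_members.csv" = out$cohorts$cohort1,
    "cohort2_members.csv" = out$cohorts$cohort2,
    "cohort1_baseline.csv" = out$cohort1$baseline$table,
    "cohort1_baseline_tests.csv" = out$cohort1$baseline$tests,
    "cohort1_weights.csv" = out$cohort1$weights,
    "cohort1_hr.csv" = rbind(out$cohort1$crude, out$cohort1$weighted),
    "cohort1_km.csv" = out$cohort1$km,
    "cohort1_subgroups.csv" = out$cohort1$subgroups,
    "cohort1_interactions.csv" = out$cohort1$interactions,
    "cohort1_sensitivity.csv" = out$cohort1$sensitivity,
    "cohort1_events.csv" = out$cohort1$events,
    "cohort2_hr.csv" = rbind(out$cohort2$crude, out$cohort2$weighted),
    "cohort2_km.csv" = out$cohort2$km,
    "cohort2_events.csv" = out$cohort2$events
  )
  if (!is.null(out$planted_vs_estimated))
    files[["planted_vs_estimated.csv"]] <- out$planted_vs_estimated
  manifest <- rbindlist(lapply(names(files), function(f) {
    path <- file.path(out_dir, f)
    write_table(files[[f]], path, allow_empty = TRUE)
    data.table(output = f, rows = nrow(files[[f]]),
               md5 = unname(tools::md5sum(path)))
  }))
  manifest[, seconds := NA_real_]
  stage_dt <- data.table(output = paste0("stage:", names(out$stage_seconds)),
                         rows = NA_integer_, md5 = NA_character_,
                         seconds = round(unlist(out$stage_seconds), 3))
  write_table(rbind(manifest, stage_dt), file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}
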