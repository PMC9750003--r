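#' Run configuration for the full pipeline
#'
#' Collects the inputs and flags of a reproducible run.  Every flag
#' defaults to the model's reference choice (documented per module).
#'
#' @param parameter_table Path to a parameter table, or `NULL` for the
#'   bundled base case.
#' @param cohort `"synthetic"` (generate from the parameters) or a path to
#'   a patient-level cohort CSV.
#' @param seed Integer seed for all stochastic stages.
#' @param outputs_dir Directory receiving all artifacts.
#' @param psa_draws Number of PSA simulations (default 10,000).
#' @param run_psa Run the probabilistic analysis (default `TRUE`).
#' @param scenarios Scenario names to evaluate.
#' @param options Run options forwarded to [ec_parameters()].
#' @return List of class `ec_runconfig`.
#' @export
run_config <- function(parameter_table = NULL, cohort = "synthetic",
                       seed = 1, outputs_dir = "results",
                       psa_draws = 10000, run_psa = TRUE,
                       scenarios = c("proportional_morbidity",
                                     "retraining_every_5y"),
                       options = list()) {
  structure(list(parameter_table = parameter_table, cohort = cohort,
                 seed = seed, outputs_dir = outputs_dir,
                 psa_draws = psa_draws, run_psa = run_psa,
                 scenarios = scenarios, options = options),
            class = "ec_runconfig")
}

load_config_params <- function(config) {
  if (is.null(config$parameter_table)) {
    ec_parameters(options = config$options)
  } else {
    load_parameter_table(config$parameter_table, options = config$options)
  }
}

provenance <- function(params, config, extra = list()) {
  c(list(parameter_hash = rlang::hash(params$table),
         seed = config$seed,
         options = params$options),
    extra)
}

write_provenance <- function(params, config, path, extra = list()) {
  jsonlite::write_json(provenance(params, config, extra), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the deterministic cost-effectiveness analysis and write results
#'
#' Evaluates both arms at base-case values, writes the arm-level and
#' incremental results table (`cea_results.csv`), the per-arm cost
#' breakdown (`cost_breakdown.csv`) and a provenance record
#' (`cea_provenance.json`) echoing the parameter hash, seed and flags.
#' The deterministic outputs are byte-identical across runs and do not
#' depend on the seed.
#'
#' @param config `ec_runconfig` from [run_config()].
#' @return The [run_base_case()] result, invisibly; files under
#'   `config$outputs_dir`.
#' @export
run_cea <- function(config = run_config()) {
  stopifnot(inherits(config, "ec_runconfig"))
  params <- load_config_params(config)
  dir.create(config$outputs_dir, recursive = TRUE, showWarnings = FALSE)
  base <- run_base_case(params)
  utils::write.csv(cea_table(base),
                   file.path(config$outputs_dir, "cea_results.csv"),
                   row.names = FALSE)
  write_cost_breakdown(list(no_toolkit = base$no_toolkit$cost,
                            toolkit = base$toolkit$cost),
                       file.path(config$outputs_dir, "cost_breakdown.csv"))
  write_provenance(params, config,
                   file.path(config$outputs_dir, "cea_provenance.json"))
  invisible(base)
}

#' Run the full analysis bundle
#'
#' Runs, in order: the deterministic CEA, the one-way tornado analysis,
#' the probabilistic sensitivity analysis (unless disabled), the scenario
#' analyses, and the national-scale-up budget-impact projection, writing
#' each stage's artifacts under `config$outputs_dir`:
#' `cea_results.csv`, `cost_breakdown.csv`, `tornado.csv`,
#' `psa_draws.csv`, `psa_summary.json`, `scenarios.csv`,
#' `bia_ledger.csv`, `bia_summary.json`, plus provenance and a run log.
#' A failing stage is recorded in the log and does not discard completed
#' stages.
#'
#' @param config `ec_runconfig`.
#' @return Named list of stage results (`NULL` for failed stages),
#'   invisibly.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "ec_runconfig"))
  params <- load_config_params(config)
  out <- config$outputs_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  results <- list()

  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      log_lines <<- c(log_lines,
                      sprintf("FAIL %s: %s", name, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) log_lines <<- c(log_lines, paste("OK", name))
    results[[name]] <<- res
    res
  }

  stage("cea", function() run_cea(config))

  stage("tornado", function() {
    tor <- tornado(params)
    utils::write.csv(tor, file.path(out, "tornado.csv"),
                     row.names = FALSE)
    tor
  })

  if (isTRUE(config$run_psa)) {
    stage("psa", function() {
      psa <- run_psa(params, n_draws = config$psa_draws,
                     seed = config$seed)
      utils::write.csv(psa$draws, file.path(out, "psa_draws.csv"),
                       row.names = FALSE)
      jsonlite::write_json(psa$summary,
                           file.path(out, "psa_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      psa
    })
  }

  stage("scenarios", function() {
    rows <- do.call(rbind, lapply(config$scenarios, function(sc) {
      r <- scenario(sc, params)
      data.frame(scenario = sc,
                 delta_cost = r$scenario$delta_cost,
                 dalys_averted = r$scenario$dalys_averted,
                 icer_per_daly = r$scenario$icer_per_daly,
                 dalys_averted_change = r$delta_dalys_averted,
                 cost_change = r$delta_cost_change,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rows, file.path(out, "scenarios.csv"),
                     row.names = FALSE)
    rows
  })

  stage("bia", function() {
    bia <- project_budget()
    utils::write.csv(bia$ledger, file.path(out, "bia_ledger.csv"),
                     row.names = FALSE)
    budgets <- reference_budgets()
    scale <- scale_up_outcomes(params)
    summary <- list(
      new_mix_total = bia$totals$new_mix_total,
      old_mix_total = bia$totals$old_mix_total,
      budget_impact_total = bia$totals$budget_impact_total,
      year1_budget_impact = bia$totals$year1_budget_impact,
      share_total_health_budget_pct = round(
        budget_share(bia$totals$budget_impact_total,
                     budgets$total_health_budget), 2),
      share_rrh_budget_pct = round(
        budget_share(bia$totals$budget_impact_total, budgets$rrh_budget),
        2),
      model_annual = scale$annual,
      model_horizon = scale$horizon,
      model_roi_pct = round(roi(scale$horizon$economic_gains,
                                bia$totals$new_mix_total)))
    jsonlite::write_json(summary, file.path(out, "bia_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    bia
  })

  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(results)
}
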