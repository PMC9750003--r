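#' Evaluate one strategy arm of the model
#'
#' Builds the arm's decision tree at the supplied parameter values, rolls
#' it back analytically over the annual cohort, and values the terminal
#' states: health outcomes via [arm_health()] and societal costs via
#' [arm_costs()].  The toolkit arm carries the intervention delivery cost
#' (renewed every five years over the horizon when the retraining scenario
#' option is on); the comparator carries none.
#'
#' @param params `ec_params` object.
#' @param arm `"pre"` (no toolkit) or `"post"` (toolkit).
#' @param pv Optional perturbed parameter-value vector (defaults to base
#'   values); this is the hook used by the sensitivity analyses.
#' @param n_patients Cohort size (defaults to `params$options$n_patients`).
#' @return List of class `ec_arm` with elements `arm`, `n_patients`,
#'   `states`, `health` (`ec_health`), `cost` (`ec_cost`).
#' @export
evaluate_strategy <- function(params, arm = c("pre", "post"), pv = NULL,
                              n_patients = NULL) {
  stopifnot(inherits(params, "ec_params"))
  arm <- match.arg(arm)
  if (is.null(pv)) pv <- param_values(params)
  if (is.null(n_patients)) n_patients <- params$options$n_patients

  prof <- condition_profiles(pv)
  split <- disability_split(pv)
  assumptions <- model_assumptions(pv)
  opts <- params$options

  tree <- build_tree(prof, split, arm,
                     odds_scale = opts$or_on_odds_scale,
                     morbidity_multiplier = opts$morbidity_multiplier)
  states <- evaluate_tree(tree, n_patients)
  health <- arm_health(states, assumptions, split,
                       working_age_floor = opts$working_age_floor)

  intervention <- 0
  if (arm == "post") {
    unit <- unname(pv["intervention_cost"])
    intervention <- if (isTRUE(opts$retraining_every_5y)) {
      renewals <- seq(0, assumptions$time_horizon - 1e-9, by = 5)
      unit * sum((1 + assumptions$discount_rate)^(-renewals))
    } else {
      unit
    }
  }
  cost <- arm_costs(states, pv, assumptions, health, intervention,
                    options = opts)
  structure(list(arm = arm, n_patients = n_patients, states = states,
                 health = health, cost = cost),
            class = "ec_arm")
}

#' Run the base-case comparison of both arms
#'
#' @param params `ec_params` object.
#' @param pv Optional perturbed parameter-value vector.
#' @param n_patients Cohort size override.
#' @return List with `no_toolkit` and `toolkit` (`ec_arm`s) and
#'   `incremental` (`ec_incremental`).
#' @export
run_base_case <- function(params = ec_parameters(), pv = NULL,
                          n_patients = NULL) {
  pre <- evaluate_strategy(params, "pre", pv = pv, n_patients = n_patients)
  post <- evaluate_strategy(params, "post", pv = pv,
                            n_patients = n_patients)
  list(no_toolkit = pre, toolkit = post,
       incremental = incremental(pre, post))
}
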