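#' Intervention delivery cost components
#'
#' The four direct cost components of deploying the toolkit at the two
#' study sites (2020 USD): start-up/training-of-trainers, Basic Emergency
#' Care course, triage tool printing, checklist tool printing.  Their sum
#' is the printed deployment total of $5,873.  (Start-up plus BEC alone is
#' 1,683 + 3,515 = 5,198; the source prints "$5,199 by site", a rounding
#' artifact.)
#'
#' @param pv Optional named parameter-value vector.
#' @return Named list with `startup_tot`, `bec_training`, `triage_tool`,
#'   `checklist_tool`.
#' @export
intervention_cost_components <- function(pv = NULL) {
  if (is.null(pv)) pv <- param_values(ec_parameters())
  list(startup_tot = unname(pv["startup_cost"]),
       bec_training = unname(pv["bec_training_cost"]),
       triage_tool = unname(pv["triage_tool_cost"]),
       checklist_tool = unname(pv["checklist_tool_cost"]))
}

#' Total intervention cost for a deployment
#'
#' All four components (training and printed tools) scale with the number
#' of deployment units; the reference deployment (the two-site study,
#' `n_sites = 1`) costs the component sum.
#'
#' @param costs List from [intervention_cost_components()].
#' @param n_sites Number of deployment units (>= 1; the national scale-up
#'   passes 19 hospital sites against the per-site base deployment cost).
#' @return USD.
#' @export
#' @examples
#' total_intervention_cost(intervention_cost_components())  # 5873
total_intervention_cost <- function(costs, n_sites = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (any(unlist(costs) < 0)) stop("cost components must be >= 0",
                                   call. = FALSE)
  n_sites * (costs$startup_tot + costs$bec_training + costs$triage_tool +
               costs$checklist_tool)
}

#' Lifetime disability-care cost for one disabled survivor
#'
#' Amputees incur rehabilitation care (annual, only when flagged as
#' needing rehab) discounted over the horizon, plus a prosthetic renewed
#' every five years starting at `anchor_year` (11 devices over a 55-year
#' horizon with the default anchor 0).  Survivors with neurological
#' impairment require life-long care delivered by a family caretaker,
#' costed at one annual income over the horizon; the caretaker's foregone
#' income is counted here, as a care cost, and never again as a
#' productivity loss (see [arm_costs()]).
#'
#' @param state `"survive_amputation"` or `"survive_neuro"`.
#' @param rehab_flag Does this survivor need rehabilitation services?
#' @param horizon Care horizon in years.
#' @param rate Annual discount rate.
#' @param rehab_annual Annual rehabilitation cost (USD/year).
#' @param prosthetic Prosthetic device cost (USD).
#' @param caretaker_income Annual caretaker income (USD/year).
#' @param anchor_year Year of the first prosthetic (0 or 5).
#' @return USD.
#' @export
#' @examples
#' disability_lifetime_cost("survive_neuro", FALSE, 55, 0,
#'                          caretaker_income = 1354.68)  # 74507.40
disability_lifetime_cost <- function(state, rehab_flag = FALSE,
                                     horizon = 55, rate = 0.035,
                                     rehab_annual = 27.03,
                                     prosthetic = 672.50,
                                     caretaker_income = 1354.68,
                                     anchor_year = 0) {
  if (!state %in% c("survive_amputation", "survive_neuro")) {
    stop("disability costs apply only to disabled-survivor states, not '",
         state, "'", call. = FALSE)
  }
  if (state == "survive_neuro") {
    return(caretaker_income * discounted_years(horizon, rate))
  }
  renewals <- if (horizon > anchor_year) {
    seq(anchor_year, horizon - 1e-9, by = 5)
  } else {
    anchor_year
  }
  prosth <- prosthetic * sum((1 + rate)^(-renewals))
  rehab <- if (rehab_flag) rehab_annual * discounted_years(horizon, rate)
           else 0
  prosth + rehab
}

#' Acute treatment cost of a cohort
#'
#' A single average per-episode cost applies across the five sentinel
#' conditions unless per-condition costs are supplied.
#'
#' @param counts Per-condition patient counts (any non-negative numeric).
#' @param episode_cost Cost per episode, scalar or one per count.
#' @return USD.
#' @export
#' @examples
#' treatment_cost(3994)  # 60668.86
treatment_cost <- function(counts, episode_cost = 15.19) {
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  sum(counts * episode_cost)
}

#' Aggregate societal costs for one strategy arm
#'
#' Sums the four societal cost streams over the arm's terminal-state
#' table: intervention delivery (toolkit arm only), acute treatment for
#' every admitted patient, lifetime disability care (rehabilitation,
#' prosthetics, caretaker income), and human-capital productivity losses
#' from premature death and permanent work loss among disabled survivors.
#' The caretaker income stream and the neurological survivor's own
#' productivity loss are distinct person-roles; the constructor's audit
#' flag records that the caretaker's income is counted exactly once (as a
#' care cost).
#'
#' @param states Terminal-state table from [evaluate_tree()].
#' @param pv Named parameter-value vector.
#' @param assumptions List from [model_assumptions()].
#' @param health `ec_health` for the arm (supplies the productivity total).
#' @param intervention USD of intervention delivery attributed to the arm.
#' @param options Run options from an `ec_params` object.
#' @return List of class `ec_cost` with components `intervention`,
#'   `treatment`, `disability_care`, `productivity`, `total` and attribute
#'   `caretaker_counted_once = TRUE`.
#' @export
arm_costs <- function(states, pv, assumptions, health, intervention,
                      options = list(prosthetic_anchor_year = 0)) {
  counts <- if ("expected" %in% names(states)) states$expected
            else states$count
  treat <- treatment_cost(sum(counts), unname(pv["episode_cost"]))
  dis_rows <- which(states$state %in% c("survive_amputation",
                                        "survive_neuro"))
  care <- 0
  for (i in dis_rows) {
    care <- care + counts[i] * disability_lifetime_cost(
      states$state[i], states$rehab_flag[i],
      horizon = assumptions$time_horizon, rate = assumptions$discount_rate,
      rehab_annual = unname(pv["rehabilitation_cost"]),
      prosthetic = unname(pv["prosthetic_cost"]),
      caretaker_income = assumptions$annual_income,
      anchor_year = options$prosthetic_anchor_year %||% 0)
  }
  cost_result(intervention = intervention, treatment = treat,
              disability_care = care,
              productivity = health$productivity_loss)
}

#' Construct a cost result
#'
#' @param intervention,treatment,disability_care,productivity USD
#'   components.
#' @return `ec_cost` list whose `total` is the component sum; the
#'   `caretaker_counted_once` attribute asserts the double-counting audit.
#' @export
cost_result <- function(intervention = 0, treatment = 0,
                        disability_care = 0, productivity = 0) {
  comps <- c(intervention = intervention, treatment = treatment,
             disability_care = disability_care, productivity = productivity)
  if (any(comps < 0)) stop("cost components must be >= 0", call. = FALSE)
  structure(c(as.list(comps), list(total = sum(comps))),
            caretaker_counted_once = TRUE, class = "ec_cost")
}

#' @export
print.ec_cost <- function(x, ...) {
  cat(sprintf(
    "<ec_cost> intervention $%.0f + treatment $%.0f + disability $%.0f + productivity $%.0f = $%.0f\n",
    x$intervention, x$treatment, x$disability_care, x$productivity,
    x$total))
  invisible(x)
}

#' Write a cost breakdown as CSV
#'
#' @param costs Named list of `ec_cost` objects, one per arm.
#' @param path Destination CSV (columns component, arm, usd).
#' @return `path`, invisibly.
#' @export
write_cost_breakdown <- function(costs, path) {
  rows <- do.call(rbind, lapply(names(costs), function(arm) {
    x <- costs[[arm]]
    data.frame(component = c("intervention", "treatment", "disability_care",
                             "productivity", "total"),
               arm = arm,
               usd = c(x$intervention, x$treatment, x$disability_care,
                       x$productivity, x$total),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
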