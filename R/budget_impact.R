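#' National scale-up configuration
#'
#' Reference configuration of the five-year, undiscounted, payer-
#' perspective budget-impact projection: the toolkit deployed at all 19
#' regional referral hospitals, each seeing about 2,000 emergency-unit
#' patients per year, with a 15% increase in treatment-resource
#' utilisation attributable to training and checklist use.
#'
#' @param n_hospitals Number of regional referral hospitals (19).
#' @param patients_per_site Annual emergency-unit patients per site
#'   (2,000).
#' @param horizon_years Projection horizon (5).
#' @param utilization_uplift Relative increase in resource utilisation
#'   (0.15).
#' @param discount_rate Annual discount rate (0: budget planning is
#'   undiscounted).
#' @return List of class `ec_scaleup`.
#' @export
scale_up_config <- function(n_hospitals = 19, patients_per_site = 2000,
                            horizon_years = 5, utilization_uplift = 0.15,
                            discount_rate = 0) {
  if (n_hospitals < 1 || patients_per_site < 1 || horizon_years < 0) {
    stop("counts must be positive", call. = FALSE)
  }
  if (utilization_uplift < 0) stop("uplift must be >= 0", call. = FALSE)
  structure(list(n_hospitals = n_hospitals,
                 patients_per_site = patients_per_site,
                 horizon_years = horizon_years,
                 utilization_uplift = utilization_uplift,
                 discount_rate = discount_rate),
            class = "ec_scaleup")
}

#' Reference per-year budget ledger inputs
#'
#' The published five-year ledger cells for the old (no-toolkit) treatment
#' mix, and the per-year share of the treatment-cost base to which the
#' utilisation uplift applies.  The shares are calibrated from the
#' published new-mix/old-mix ratios (`(new/old - 1)/0.15`), reproducing
#' the reference ledger; they are the package's frozen defaults and can be
#' overridden.
#'
#' @return List with `treatment_old` (USD, years 1-5), `uplift_share`
#'   (fractions, years 1-5), `treatment_new_published` (USD, years 1-5,
#'   kept for reference), `intervention_published` (USD, year 1).
#' @export
bia_reference_costs <- function() {
  old <- c(1062550, 738722, 734361, 730118, 725990)
  new <- c(1160697, 829153, 824688, 820344, 816118)
  list(treatment_old = old,
       uplift_share = (new / old - 1) / 0.15,
       treatment_new_published = new,
       intervention_published = 111602)
}

#' Project the national scale-up budget ledger
#'
#' Builds the five-year new-mix versus old-mix cost ledger.  Intervention
#' costs fall entirely in year 1 (training scales with the number of
#' sites: `n_hospitals` times the per-site deployment cost); the old mix
#' has no intervention cost.  Old-mix treatment costs follow the supplied
#' per-year series (or a year-1 value spread by `trend` multipliers); the
#' new mix applies the utilisation uplift to a calibrated share of the
#' treatment-cost base, unless explicit new-mix cells are supplied.
#'
#' @param config `ec_scaleup` from [scale_up_config()].
#' @param intervention_cost_y1 Year-1 intervention cost; default
#'   `n_hospitals` x the per-site deployment cost (5,873.80 USD).
#' @param treatment_old Per-year old-mix treatment costs (USD); default
#'   the reference ledger series.
#' @param treatment_new Optional explicit per-year new-mix treatment
#'   costs; when `NULL`, computed as
#'   `treatment_old * (1 + uplift * uplift_share)`.
#' @param uplift_share Share of the treatment-cost base subject to the
#'   uplift, recycled over years; default the calibrated reference shares.
#' @param trend Optional per-year multipliers applied to
#'   `treatment_old[1]` instead of an explicit series.
#' @return List of class `ec_bia`: `ledger` (data.frame, one row per
#'   year), `totals` (new-mix total, old-mix total, budget-impact total,
#'   year-1 budget impact).
#' @export
project_budget <- function(config = scale_up_config(),
                           intervention_cost_y1 = NULL,
                           treatment_old = NULL, treatment_new = NULL,
                           uplift_share = NULL, trend = NULL) {
  stopifnot(inherits(config, "ec_scaleup"))
  h <- config$horizon_years
  if (h < 1) stop("empty ledger: horizon_years must be >= 1",
                  call. = FALSE)
  ref <- bia_reference_costs()
  if (is.null(intervention_cost_y1)) {
    intervention_cost_y1 <- config$n_hospitals * 5873.80
  }
  if (is.null(treatment_old)) {
    treatment_old <- if (!is.null(trend)) {
      ref$treatment_old[1] * trend
    } else {
      ref$treatment_old
    }
  }
  if (length(treatment_old) != h) {
    stop("treatment_old must supply one value per year (", h, ")",
         call. = FALSE)
  }
  if (is.null(treatment_new)) {
    if (is.null(uplift_share)) uplift_share <- ref$uplift_share
    uplift_share <- rep_len(uplift_share, h)
    treatment_new <- treatment_old *
      (1 + config$utilization_uplift * uplift_share)
  }
  if (length(treatment_new) != h) {
    stop("treatment_new must supply one value per year (", h, ")",
         call. = FALSE)
  }

  intervention_new <- c(intervention_cost_y1, rep(0, h - 1))
  ledger <- data.frame(
    year = seq_len(h),
    intervention_cost_new = intervention_new,
    treatment_cost_new = treatment_new,
    intervention_cost_old = rep(0, h),
    treatment_cost_old = treatment_old)
  ledger$budget_impact <-
    (ledger$intervention_cost_new + ledger$treatment_cost_new) -
    (ledger$intervention_cost_old + ledger$treatment_cost_old)

  totals <- list(
    new_mix_total = sum(ledger$intervention_cost_new +
                          ledger$treatment_cost_new),
    old_mix_total = sum(ledger$intervention_cost_old +
                          ledger$treatment_cost_old),
    budget_impact_total = sum(ledger$budget_impact),
    year1_budget_impact = ledger$budget_impact[1])
  structure(list(ledger = ledger, totals = totals, config = config),
            class = "ec_bia")
}

#' @export
print.ec_bia <- function(x, ...) {
  cat(sprintf(
    "<ec_bia> %d years | new mix $%.0f | old mix $%.0f | budget impact $%.0f\n",
    nrow(x$ledger), x$totals$new_mix_total, x$totals$old_mix_total,
    x$totals$budget_impact_total))
  invisible(x)
}

#' Return on investment
#'
#' `100 * gains / investment` (gains relative to investment, not net
#' gains: the reporting convention of the source analysis, rounded to the
#' nearest integer percent when reported).
#'
#' @param economic_gains Societal economic gains (USD).
#' @param investment Scale-up investment (USD, > 0).
#' @return Percent (unrounded numeric).
#' @export
#' @examples
#' round(roi(29880949, 4562588))  # 655
roi <- function(economic_gains, investment) {
  if (any(investment <= 0)) stop("investment must be > 0", call. = FALSE)
  100 * economic_gains / investment
}

#' Budget share of a budget impact
#'
#' @param budget_impact USD.
#' @param reference_budget USD (> 0).
#' @return Percent, reported at two decimals by the pipeline.
#' @export
#' @examples
#' round(budget_share(570862, 643941532.62), 2)  # 0.09
budget_share <- function(budget_impact, reference_budget) {
  if (any(reference_budget <= 0)) {
    stop("reference_budget must be > 0", call. = FALSE)
  }
  100 * budget_impact / reference_budget
}

#' Reference national budgets (2018/2019, converted at 3,675 UGX/USD)
#'
#' @return List with `total_health_budget` and `rrh_budget` in USD.
#' @export
reference_budgets <- function() {
  list(total_health_budget = 643941532.62, rrh_budget = 34772842.76)
}

#' Health outcomes of the national scale-up
#'
#' Evaluates the two-arm model on the scaled annual cohort
#' (`n_hospitals * patients_per_site` patients) at the budget-impact
#' discount rate (0: non-discounted outcomes, as budget projections
#' report), returning annual and horizon totals.  Deaths averted scale
#' linearly with the cohort at fixed rates.
#'
#' @param params `ec_params` object.
#' @param config `ec_scaleup` object.
#' @return List: `annual` (deaths averted, LYS, DALYs averted, downstream
#'   societal savings in USD/year) and `horizon` (the same times
#'   `horizon_years`, plus `economic_gains`).
#' @export
scale_up_outcomes <- function(params = ec_parameters(),
                              config = scale_up_config()) {
  pv <- param_values(params)
  pv["discount_rate"] <- config$discount_rate
  n_annual <- config$n_hospitals * config$patients_per_site
  base <- run_base_case(params, pv = pv, n_patients = n_annual)
  inc <- base$incremental
  # downstream savings exclude the intervention outlay itself
  savings <- -(inc$delta_cost - base$toolkit$cost$intervention)
  annual <- list(deaths_averted = base$no_toolkit$health$deaths -
                   base$toolkit$health$deaths,
                 lys = inc$lys,
                 dalys_averted = inc$dalys_averted,
                 downstream_savings = savings)
  horizon <- lapply(annual, function(v) v * config$horizon_years)
  horizon$economic_gains <- horizon$downstream_savings
  list(annual = annual, horizon = horizon)
}
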