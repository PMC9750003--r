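#!/usr/bin/env Rscript
# National scale-up: five-year, undiscounted budget-impact ledger for
# deployment at all 19 regional referral hospitals (15% utilisation
# uplift on the calibrated share of the treatment-cost base), budget
# shares against the national and referral-hospital budgets, and return
# on investment.

suppressPackageStartupMessages(library(ectoolkit))

dir.create("results", showWarnings = FALSE)
params <- ec_parameters()

bia <- project_budget()
write.csv(bia$ledger, "results/bia_ledger.csv", row.names = FALSE)
cat("Five-year ledger (USD):\n")
print(bia$ledger, digits = 8)
cat(sprintf(
  "\nNew mix $%.0f | old mix $%.0f | budget impact $%.0f (year 1: $%.0f)\n",
  bia$totals$new_mix_total, bia$totals$old_mix_total,
  bia$totals$budget_impact_total, bia$totals$year1_budget_impact))

budgets <- reference_budgets()
cat(sprintf("Share of total health budget: %.2f%% | of RRH budget: %.2f%%\n",
            budget_share(bia$totals$budget_impact_total,
                         budgets$total_health_budget),
            budget_share(bia$totals$budget_impact_total,
                         budgets$rrh_budget)))

scale <- scale_up_outcomes(params)
cat(sprintf(
  "\nModelled scale-up (38,000 patients/year): %.0f deaths and %.0f DALYs averted annually\n",
  scale$annual$deaths_averted, scale$annual$dalys_averted))
cat(sprintf("Five-year downstream savings $%.0f -> ROI %.0f%%\n",
            scale$horizon$economic_gains,
            roi(scale$horizon$economic_gains, bia$totals$new_mix_total)))

summary <- list(totals = bia$totals,
                shares = list(
                  total_health_pct = round(budget_share(
                    bia$totals$budget_impact_total,
                    budgets$total_health_budget), 2),
                  rrh_pct = round(budget_share(
                    bia$totals$budget_impact_total, budgets$rrh_budget),
                    2)),
                scale_up = scale)
jsonlite::write_json(summary, "results/bia_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
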