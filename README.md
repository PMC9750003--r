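# ectoolkit

Decision-analytic cost-effectiveness and budget-impact modelling of a
multi-strategy emergency-care toolkit intervention (basic emergency-care
training, triage tool, trauma checklist, resuscitation-area
reorganisation) deployed in Ugandan regional referral hospitals. The
package is for health economists and health-system planners who want to
re-run, probe or extend the analysis: every stage — parameters, decision
tree, valuation, costing, incremental comparison, sensitivity analyses
and national scale-up — is an ordinary, tested R function.

## The model

A two-arm decision tree over one annual cohort of patients presenting
with one of five sentinel conditions *c* (road-traffic injury,
post-partum haemorrhage, asthma, paediatric pneumonia, paediatric
diarrhoea). Each patient dies within 48 hours with probability
*p\_c* (no-toolkit arm) or *p\_c · OR\_c* (toolkit arm, the odds ratio
applied as a risk multiplier, capped at 1). Road-traffic-injury
survivors face disability sub-branches (none / amputation /
neurological deficit, with rehabilitation need). Outcomes are valued as
DALYs = YLL + YLD, with

* YLL per death = annuity(life expectancy − median age, *r*),
* YLD per disabled survivor = disability weight × annuity(horizon, *r*),

both discounted at *r* = 3.5%/year, and costs from a societal
perspective in 2020 USD: toolkit deployment ($5,873), acute treatment
($15.19/episode), disability care (rehabilitation, prosthetics renewed
five-yearly, life-long caretaker income for neurological survivors) and
human-capital productivity losses (annual income × discounted working
years lost). Strategies are compared by incremental cost per DALY
averted (ICER) with net-monetary-benefit verdicts at willingness-to-pay
$11–$289/DALY; uncertainty is handled by a one-way tornado analysis and
a 10,000-draw probabilistic sensitivity analysis over gamma/beta/
lognormal distributions fitted to each parameter's base value and range.
A five-year, undiscounted budget-impact ledger projects national
scale-up to 19 hospitals with a 15% resource-utilisation uplift.

The per-condition composition of the registry cohort was never
published; the bundled shares (RTI 0.55, PPH 0.10, asthma 0.08,
paediatric pneumonia 0.15, paediatric diarrhoea 0.12) are documented
assumptions, so absolute headline numbers track the published analysis
in structure and direction rather than digit-for-digit. See
`vignettes/toolkit-cea-methods.Rmd` for every design choice.

## Worked example

```r
library(ectoolkit)

params <- ec_parameters()          # bundled base-case inputs
base <- run_base_case(params)
base$incremental
#> <ec_incremental> delta cost $-2317096 | DALYs averted 2029.7 |
#>   ICER $-1141.58/DALY [dominant]
```

Deploying the toolkit costs $5,873 up front but averts ~88 deaths in
the 3,994-patient annual cohort, saving $2.32M in downstream societal
costs and 2,030 discounted DALYs: the toolkit *dominates* (cheaper and
more effective), so the negative ICER of −$1,142 per DALY averted means
savings per unit of health gained, and the choice is cost-effective at
every willingness-to-pay threshold.

```r
tor <- tornado(params)
head(tor[, c("parameter", "icer_at_low", "icer_at_high", "swing")], 3)
#>         parameter icer_at_low icer_at_high     swing
#> 1   annual_income     -391.65      -2581.2 2189.5057
#> 2   discount_rate    -1223.89      -1108.5  115.3957
#> 3 p_no_disability    -1048.43      -1160.4  111.9637

psa <- run_psa(params, n_draws = 10000, seed = 1)
psa$summary$prob_cost_saving
#> [1] 1

bia <- project_budget()            # 19-hospital, 5-year scale-up ledger
bia$totals
#> $new_mix_total      4562602.2
#> $old_mix_total      3991741
#> $budget_impact_total 570861.2
#> $year1_budget_impact 209749.2
round(budget_share(bia$totals$budget_impact_total,
                   reference_budgets()$total_health_budget), 2)
#> [1] 0.09
```

The tornado says the result is driven almost entirely by the annual
cash income used in the human-capital valuation (a swing of
~$2,190/DALY, an order of magnitude above every other parameter);
every PSA draw is cost-saving; and national scale-up adds $570,861 over
five years — 0.09% of the national health budget (1.64% of the
referral-hospital budget).

The numbered drivers under `analysis/` run the full workflow and write
tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic registry + recovery
Rscript analysis/02_base_case_cea.R     # arm totals, ICER, WTP verdicts
Rscript analysis/03_sensitivity.R       # tornado, PSA, scenarios
Rscript analysis/04_budget_impact.R     # scale-up ledger, shares, ROI
```

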