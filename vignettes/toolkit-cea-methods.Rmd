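---
title: "Modelling the cost-effectiveness of an emergency-care toolkit: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cost-effectiveness of an emergency-care toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectoolkit)
```

## The decision problem

A multi-strategy emergency-care toolkit (basic emergency-care training,
triage tool, trauma checklist, resuscitation-area reorganisation) was
deployed at two Ugandan public hospitals. Routine quality-improvement
registries recorded 48-hour case-fatality for five sentinel conditions —
road-traffic injury (RTI), post-partum haemorrhage (PPH), asthma,
paediatric pneumonia and paediatric diarrhoea — for one year before
(2,241 patients) and one year after (1,753 patients) the deployment.
`ectoolkit` models whether deploying the toolkit is good value from a
societal perspective, and whether scaling it to all 19 regional referral
hospitals is affordable.

The model is a two-arm decision tree evaluated over one annual cohort.
Each patient draws a sentinel condition (cohort shares), then either dies
within 48 hours or survives. The no-toolkit arm uses the
pre-intervention case-fatality rates; the toolkit arm multiplies each
rate by the condition's published odds ratio (`derive_post_cfr()`). That
multiplicative, risk-scale application is deliberately faithful to the
source analysis; the statistically orthodox odds-scale conversion is
available behind the `or_on_odds_scale` flag and matters little at these
event rates. Survivors of every condition except RTI return to full
health. RTI survivors avoid disability with probability 0.962; the
disabled split 0.788/0.212 into amputation versus neurological deficit,
and rehabilitation need covers 0.115 of disabled survivors, assigned
within the amputation branch first (the source never places this
probability in its tree; the assignment is config-overridable).

## Valuation

Health burden is measured in DALYs: years of life lost (YLL) from the
condition's median age (2 years for the paediatric conditions, 26
otherwise) to the life expectancy of 68.6 years, plus years lived with
disability (YLD) weighted 0.275 (amputation) or 0.359 (neurological
deficit) over the 55-year time horizon. Costs and outcomes are both
discounted at 3.5%/year. Discounting uses an annual annuity sum with the
fractional final year weighted proportionally; the continuous closed
form `(1-(1+r)^-d)/r` agrees within 0.5% across rates 0–5% and durations
1–67 years and serves as the test oracle. Note one convention inherited
from the source: disabled survivors accrue YLD and care costs over the
55-year horizon even though median age 26 plus 55 exceeds the 68.6-year
life expectancy.

Costs take a societal perspective in 2020 USD (UGX converted once at
3,675/USD): the toolkit deployment itself ($5,873: start-up/training
$1,683, basic emergency-care course $3,515, triage tool $172, checklist
$503), acute treatment at $15.19 per episode (uniform across conditions,
and identical between arms, so it never drives the incremental result),
disability care (rehabilitation $27.03/year where needed; a $672.50
prosthetic renewed every five years from year 0, eleven devices over the
horizon, anchor configurable to year 5; life-long family caretaker time
for neurological survivors valued at one annual income), and
human-capital productivity losses.

Productivity valuation follows the human-capital approach: one annual
cash income ($1,354.68) per working year lost between
`max(age, working_age_floor)` and life expectancy. The working-age floor
defaults to 15 — income cannot be lost at age 2 — and can be set to 0
for a naive reading; the choice materially affects paediatric deaths and
is echoed into every provenance record. Deaths and amputee survivors
(assumed never to return to work) incur the full loss. For a
neurological survivor exactly one household income stream is counted:
the caretaker's, as a care cost. Counting the survivor's own foregone
income as well would double-count, and `arm_costs()` asserts this audit
via the `caretaker_counted_once` attribute.

## What is assumed, not published

The registry's per-condition patient counts were never published. The
cohort shares default to RTI 0.55, PPH 0.10, asthma 0.08, paediatric
pneumonia 0.15, paediatric diarrhoea 0.12 — an RTI-dominant mix
(both sites were chosen for trauma volume on major thoroughfares) with a
sizeable paediatric fraction. They are plainly flagged as assumptions:
they live in the parameter table, are user-configurable, and the one-way
sensitivity analysis varies the RTI share ±25% (renormalising the other
shares). Headline absolute numbers — deaths averted, arm cost totals —
depend directly on this mix, which is why the test suite asserts
structural properties (path-enumeration identity, microsimulation
convergence, parameter recovery, PSA/base-case consistency, dominance)
rather than the published absolute values.

Ranges for the five pre-intervention case-fatality rates are also
unpublished; the probabilistic analysis assigns each ±2 binomial
standard errors at the assumed per-condition sample size.

## Sampling distributions

`fit_distribution()` moment-matches every family so the fitted mean
equals the base value — the probabilistic analysis then centres on the
base case, which the acceptance property (PSA mean within 3 Monte-Carlo
SE of the deterministic result at 10,000 draws) verifies end-to-end.

* **Costs** are gamma, `sd = (high-low)/3.92`, except annual income,
  whose printed range is a sub-regional *min/max*, not a confidence
  interval; it uses the pragmatic `sd = (high-low)/4`.
* **Probabilities** are beta via mean/variance matching.
* **Odds ratios** (RTI, pneumonia, diarrhoea) have printed intervals
  that are exactly geometric around the base value, so they are sampled
  lognormal with `sdlog = log(high/low)/3.92` and the arithmetic mean
  pinned to the base (`meanlog = log(base) - sdlog^2/2`); the implied
  interval endpoints shift by at most `exp(-sdlog^2/2)` (≈9% for RTI).
* **Degenerate odds-ratio intervals** (PPH 0–3.4e37, asthma 0–3.7e34)
  carry no usable information; sampling them would pile all mass at
  post-arm fatality 0 or 1. Instead the post/pre fatality *ratio* is
  drawn from Beta(1, (1-m)/m) with mean `m` equal to the base odds
  ratio, on [0, 1], applied to the sampled pre-intervention rate.
* **The time horizon** is lognormal, mean 55.
* **The discount rate is not sampled.** It is a policy lever, varied
  0–5% in the one-way analysis; sampling it would also bias the PSA mean
  away from the base case because the annuity is convex in the rate.
* The neurological split is always the complement of the sampled
  amputation split, so the disability branches stay a single degree of
  freedom.

Draws use a single RNG stream with a fixed parameter order (the
`PSA_DRAW_ORDER` constant: costs, case-fatality rates, odds ratios,
splits, weights, horizon), so a seed fully determines a run and the
per-draw CSV is portable.

## One-way sensitivity analysis

The default tornado varies the parameters with printed ranges among
costs, disability splits, DALY weights and model assumptions, plus the
assumed RTI cohort share. Effectiveness parameters are deliberately
excluded from the default target list: two of the five odds-ratio
intervals are degenerate, and effectiveness uncertainty is explored
jointly in the PSA. With the default mix the ranking is: annual income
(dominant, swing ≈ $2,190/DALY), then discount rate, the
disability-free survival probability and the RTI share within ≈12% of
one another (swings ≈ 115/112/102), then everything else below $3/DALY.
That near-tie is a direct consequence of the assumed RTI-dominant mix:
the swing of the disability-free probability scales with averted RTI
deaths, so a mix with fewer RTI patients would push it down the ranking.

Two structural scenarios are implemented: `proportional_morbidity`
multiplies the post-arm disability probability by 1.47 (disability
growing in proportion to the survival benefit), and
`retraining_every_5y` repeats the full deployment cost every five years
over the horizon (11 renewals at a zero rate).

## Budget impact and return on investment

The scale-up module projects a five-year, undiscounted, payer-
perspective ledger for 19 hospitals at 2,000 patients/site/year.
Intervention costs (19 × $5,873.80) fall entirely in year 1. The 15%
utilisation uplift applies to a *calibrated share* of the treatment-cost
base: the published year-on-year new/old ratios imply shares of 0.616 in
year 1 and ≈0.82 thereafter, and those frozen shares are the default, so
the reference configuration reproduces the published ledger cells. The
published per-year cells themselves sum to within $1 of the published
totals (each cell is rounded to the dollar), and the ledger identity —
budget impact = new-mix total − old-mix total, per year and in total —
is enforced exactly. ROI is reported as gains/investment (not net
gains), matching the source's 655% convention. A related $15 artifact is
documented: 19 × $5,873 = $111,587 but 19 × $5,873.80 = $111,602, which
explains the difference between the two published scale-up totals.

## The synthetic registry

`simulate_cohort()` generates patient-level data with exactly the
structure the model assumes: condition via cohort shares, death via
Bernoulli at the arm's fatality rate, age fixed at the condition median
(the model uses only medians; an `age_sd` exists for stress tests). It
emulates none of the features a real registry would add — no seasonal
or day-of-week structure, no covariates, no measurement error, no
within-site correlation — so passing recovery tests demonstrates the
estimator and generator are mutually consistent, not that the pipeline
is robust to real-world registry artifacts. `estimate_rates()` recovers
per-condition fatality rates and odds ratios with Woolf (logit-scale)
95% intervals, adding the 0.5 continuity correction whenever a cell is
empty (routinely needed for PPH and asthma post arms, echoing the
degenerate published intervals). The recovery coverage test runs the
generator in odds-scale mode so the estimand coincides with the
generating parameter; under the default risk-scale application the
implied odds ratio differs from the generating multiplier by ~2% at
these rates.

## Numerical conventions and degenerate inputs

* Branch probabilities must sum to 1 within 1e-9 at construction; the
  rollback conserves patients to 1e-6 per 2,241.
* `derive_post_cfr()` caps at 1 and is monotone in both arguments.
* Zero-width ranges with a non-fixed family, ranges inconsistent with a
  family's support, probabilities outside [0, 1] and share vectors not
  summing to 1 are all rejected at load time, with every violation
  reported at once.
* Micro-simulation samples each patient's root-to-leaf path (one
  categorical draw over the enumerated paths, distributionally
  identical to a branch-by-branch walk) and agrees with the analytic
  rollback within 3 binomial SD per state at n = 1e6.
* Problem sizes used by the shipped analyses: the annual cohort of
  3,994 patients; 10,000 PSA draws; 200 recovery replicates of 50,000
  patients per arm; 1e6-patient micro-simulation checks.

## Known limitations

* Absolute headline results inherit the assumed cohort mix; only
  structure, directions and ratios should be compared against external
  numbers.
* The human-capital approach makes results highly sensitive to annual
  income (the tornado shows it an order of magnitude above every other
  parameter) and carries its usual equity caveats.
* The 55-year YLD/care horizon can exceed remaining life expectancy for
  adult survivors (a convention inherited from the source model).
* No efficiency frontier beyond two arms, no Markov extension, no
  value-of-information analysis, and no cost-effectiveness
  acceptability curve by default (the result is dominant across the
  whole $11–$289 willingness-to-pay range; `wtp_verdicts()` covers the
  threshold question).

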