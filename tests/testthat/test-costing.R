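test_that("intervention component sum reproduces the deployment total", {
  comps <- intervention_cost_components()
  expect_equal(total_intervention_cost(comps), 5873)
  expect_equal(comps$startup_tot + comps$bec_training, 5198)
  zero <- list(startup_tot = 0, bec_training = 0, triage_tool = 0,
               checklist_tool = 0)
  expect_equal(total_intervention_cost(zero), 0)
  expect_equal(total_intervention_cost(comps, n_sites = 19), 19 * 5873)
  expect_error(total_intervention_cost(comps, n_sites = 0), ">= 1")
})

test_that("lifetime disability costs follow the published care streams", {
  expect_equal(
    disability_lifetime_cost("survive_neuro", FALSE, horizon = 55,
                             rate = 0, caretaker_income = 1354.68),
    74507.40, tolerance = 1e-9)
  # 55 years of rehab plus 11 prosthetic renewals at t = 0, 5, ..., 50
  expect_equal(
    disability_lifetime_cost("survive_amputation", TRUE, horizon = 55,
                             rate = 0, rehab_annual = 27.03,
                             prosthetic = 672.50),
    55 * 27.03 + 11 * 672.50, tolerance = 1e-9)
  expect_equal(
    disability_lifetime_cost("survive_amputation", TRUE, horizon = 55,
                             rate = 0), 8884.15, tolerance = 1e-9)
  # empty horizon: the first prosthetic only; no neuro care
  expect_equal(disability_lifetime_cost("survive_amputation", FALSE,
                                        horizon = 0, rate = 0), 672.50)
  expect_equal(disability_lifetime_cost("survive_neuro", FALSE,
                                        horizon = 0, rate = 0), 0)
  # anchor at year 5: ten devices over a 55-year horizon
  expect_equal(
    disability_lifetime_cost("survive_amputation", FALSE, horizon = 55,
                             rate = 0, anchor_year = 5), 10 * 672.50)
  # discounting shrinks the renewals stream
  expect_lt(
    disability_lifetime_cost("survive_amputation", FALSE, horizon = 55,
                             rate = 0.035),
    disability_lifetime_cost("survive_amputation", FALSE, horizon = 55,
                             rate = 0))
  expect_error(disability_lifetime_cost("survive_healthy", FALSE),
               "disabled")
})

test_that("treatment costs scale linearly with admissions", {
  expect_equal(treatment_cost(1000), 15190)
  expect_equal(treatment_cost(0), 0)
  expect_equal(treatment_cost(3994), 60668.86)
  expect_equal(treatment_cost(c(100, 200), c(10, 20)), 5000)
  expect_equal(treatment_cost(2 * 3994), 2 * treatment_cost(3994))
  expect_error(treatment_cost(-1), ">= 0")
})

test_that("cost results total their components and carry the audit flag", {
  cr <- cost_result(intervention = 10, treatment = 20,
                    disability_care = 30, productivity = 40)
  expect_equal(cr$total, 100, tolerance = 1e-10)
  expect_true(attr(cr, "caretaker_counted_once"))
  expect_error(cost_result(intervention = -1), ">= 0")
})

test_that("caretaker income is counted once per neurological survivor", {
  # an arm whose only non-healthy outcome is one neuro survivor:
  # the survivor's income loss must appear in the caretaker care stream
  # and nowhere in the productivity stream
  params <- ec_parameters()
  pv <- param_values(params)
  states <- data.frame(condition = "rti", state = "survive_neuro",
                       rehab_flag = FALSE, age_at_event = 26,
                       prob = 1, expected = 1)
  assumptions <- model_assumptions(pv)
  h <- arm_health(states, assumptions, disability_split(pv))
  costs <- arm_costs(states, pv, assumptions, h, intervention = 0,
                     options = params$options)
  expect_equal(h$productivity_loss, 0)
  expect_equal(costs$disability_care,
               assumptions$annual_income *
                 discounted_years(assumptions$time_horizon,
                                  assumptions$discount_rate))
  expect_true(attr(costs, "caretaker_counted_once"))
})

test_that("cost breakdown CSV mirrors the per-arm components", {
  base <- run_base_case(ec_parameters())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cost_breakdown(list(no_toolkit = base$no_toolkit$cost,
                            toolkit = base$toolkit$cost), path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 10)
  tot <- tab$usd[tab$component == "total" & tab$arm == "toolkit"]
  expect_equal(tot, base$toolkit$cost$total)
})
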