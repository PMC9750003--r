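params <- ec_parameters()

test_that("simulated cohorts honour the requested arm sizes and seed", {
  cohort <- simulate_cohort(params, seed = 1)
  expect_equal(sum(cohort$arm == "pre"), 2241)
  expect_equal(sum(cohort$arm == "post"), 1753)
  expect_true(all(cohort$condition %in%
                    c("rti", "pph", "asthma", "paediatric_pneumonia",
                      "paediatric_diarrhoea")))
  expect_true(all(cohort$age >= 0))
  again <- simulate_cohort(params, seed = 1)
  expect_identical(as.data.frame(cohort), as.data.frame(again))
  other <- simulate_cohort(params, seed = 2)
  expect_false(identical(as.data.frame(cohort), as.data.frame(other)))
})

test_that("zero case-fatality rates yield a deathless cohort", {
  pv <- param_values(params)
  pv[grepl("^cfr_pre_", names(pv))] <- 0
  cohort <- simulate_cohort(params, n_pre = 500, n_post = 500, seed = 3,
                            pv = pv)
  expect_equal(sum(cohort$died_48h), 0)
})

test_that("degenerate cohort-share configurations are rejected", {
  pv <- param_values(params)
  pv[grepl("^share_", names(pv))] <- 0
  expect_error(simulate_cohort(params, pv = pv, seed = 1), "shares")
  expect_error(simulate_cohort(params, n_pre = 0, seed = 1), "positive")
})

test_that("odds-ratio estimation matches the hand-computed cross ratio", {
  cohort <- data.frame(
    arm = rep(c("pre", "post"), c(100, 100)),
    condition = "rti",
    died_48h = c(rep(TRUE, 10), rep(FALSE, 90),
                 rep(TRUE, 5), rep(FALSE, 95)))
  est <- estimate_rates(cohort)
  expect_equal(est$odds_ratio, (5 / 95) / (10 / 90), tolerance = 1e-12)
  expect_equal(est$odds_ratio, 0.4737, tolerance = 1e-4)
  expect_equal(est$cfr_pre, 0.10)
  expect_equal(est$cfr_post, 0.05)
  # Woolf logit-scale interval
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 5 + 1 / 95)
  expect_equal(est$or_low, est$odds_ratio * exp(-qnorm(0.975) * se))
  expect_equal(est$or_high, est$odds_ratio * exp(qnorm(0.975) * se))
  expect_false(est$continuity_corrected)
})

test_that("identical arms estimate an odds ratio of one", {
  half <- data.frame(arm = "pre", condition = "pph",
                     died_48h = rep(c(TRUE, FALSE), c(7, 93)))
  both <- rbind(half, transform(half, arm = "post"))
  expect_equal(estimate_rates(both)$odds_ratio, 1)
})

test_that("estimation is invariant to record order", {
  cohort <- simulate_cohort(params, n_pre = 2000, n_post = 2000, seed = 4)
  shuffled <- cohort[sample.int(nrow(cohort)), ]
  expect_equal(estimate_rates(cohort), estimate_rates(shuffled))
})

test_that("zero cells trigger the 0.5 continuity correction", {
  cohort <- data.frame(
    arm = rep(c("pre", "post"), c(100, 100)),
    condition = "asthma",
    died_48h = c(rep(TRUE, 10), rep(FALSE, 90), rep(FALSE, 100)))
  est <- estimate_rates(cohort)
  expect_true(est$continuity_corrected)
  expect_equal(est$odds_ratio, (0.5 / 100.5) / (10.5 / 90.5))
  expect_true(is.finite(est$or_low) && is.finite(est$or_high))
})

test_that("a condition absent from one arm is reported by name", {
  cohort <- data.frame(arm = c("pre", "pre"), condition = "rti",
                       died_48h = c(TRUE, FALSE))
  expect_error(estimate_rates(cohort), "rti")
})

test_that("estimated rates converge on the generating parameters", {
  pv <- single_condition_pv(params, "rti")
  est <- estimate_rates(simulate_cohort(params, n_pre = 40000,
                                        n_post = 40000, seed = 5, pv = pv))
  se_pre <- sqrt(0.0314 * (1 - 0.0314) / 40000)
  expect_lt(abs(est$cfr_pre - 0.0314), 4 * se_pre)
  post_true <- derive_post_cfr(0.0314, 0.265)
  se_post <- sqrt(post_true * (1 - post_true) / 40000)
  expect_lt(abs(est$cfr_post - post_true), 4 * se_post)
  # the estimated odds-ratio interval covers the implied true odds ratio
  or_true <- (post_true / (1 - post_true)) / (0.0314 / (1 - 0.0314))
  expect_lt(est$or_low, or_true)
  expect_gt(est$or_high, or_true)
})

test_that("cohorts round-trip through CSV with their provenance sidecar", {
  cohort <- simulate_cohort(params, n_pre = 50, n_post = 40, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_cohort(path)
  expect_equal(as.data.frame(cohort), as.data.frame(back))
  expect_equal(attr(back, "seed"), 6)
})
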