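test_that("bundled default table carries the published base case", {
  params <- load_parameter_table(ec_parameter_file())
  pv <- param_values(params)
  prof <- condition_profiles(pv)
  expect_equal(prof$pre_cfr,
               c(0.0314, 0.0172, 0.0111, 0.0632, 0.0267))
  expect_equal(prof$odds_ratio_post,
               c(0.265, 0.000335, 0.00367, 0.423, 0.5742))
  expect_equal(prof$median_age, c(26, 26, 26, 2, 2))
  expect_equal(sum(prof$cohort_share), 1, tolerance = 1e-12)
  expect_equal(model_assumptions(pv)$discount_rate, 0.035)
  expect_equal(model_assumptions(pv)$life_expectancy, 68.6)
  split <- disability_split(pv)
  expect_equal(split$p_amputation_given_disabled +
                 split$p_neuro_given_disabled, 1)
})

test_that("validation enumerates every violation at once", {
  tab <- default_parameter_table()
  tab$base[tab$name == "cfr_pre_rti"] <- 1.2   # probability out of bounds
  tab$base[tab$name == "episode_cost"] <- -1   # gamma support violation
  tab$low[tab$name == "prosthetic_cost"] <- 1e6 # base outside range
  errs <- validate_parameter_table(tab)
  expect_true(any(grepl("cfr_pre_rti", errs)))
  expect_true(any(grepl("episode_cost", errs)))
  expect_true(any(grepl("prosthetic_cost", errs)))
  expect_gte(length(errs), 3)
  expect_error(ec_parameters(table = tab), "cfr_pre_rti")
})

test_that("missing parameters are named in the schema error", {
  tab <- default_parameter_table()
  tab <- tab[tab$name != "annual_income", ]
  expect_match(validate_parameter_table(tab),
               "missing parameter: annual_income", all = FALSE)
})

test_that("uniform cohort shares load when they sum to one", {
  tab <- default_parameter_table()
  tab$base[grepl("^share_", tab$name)] <- 0.2
  tab$low[tab$name == "share_rti"] <- 0.15
  tab$high[tab$name == "share_rti"] <- 0.25
  params <- ec_parameters(table = tab)
  expect_equal(sum(condition_profiles(param_values(params))$cohort_share), 1)
})

test_that("parameter tables round-trip bit-for-bit through CSV and JSON", {
  params <- ec_parameters()
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_parameter_table(params, path)
    expect_identical(load_parameter_table(path)$table, params$table)
  }
})

test_that("post-intervention CFR is the capped risk-scale product", {
  expect_equal(derive_post_cfr(0.0314, 0.265), 0.008321, tolerance = 1e-9)
  expect_equal(derive_post_cfr(0.0632, 0.423), 0.0267336,
               tolerance = 1e-9)
  p <- seq(0, 1, by = 0.05)
  expect_equal(derive_post_cfr(p, 1.0), p)       # identity odds ratio
  expect_equal(derive_post_cfr(0.6, 5), 1)       # capped at 1
  expect_error(derive_post_cfr(-0.1, 1), "pre_cfr")
  expect_error(derive_post_cfr(0.1, -1), "odds_ratio")
})

test_that("post-CFR derivation is monotone in both arguments", {
  ps <- seq(0.01, 0.9, length.out = 12)
  ors <- seq(0.05, 3, length.out = 12)
  for (or in ors) {
    expect_true(all(diff(derive_post_cfr(ps, or)) >= 0))
  }
  for (p in ps) {
    expect_true(all(diff(derive_post_cfr(p, ors)) >= 0))
  }
  expect_true(all(derive_post_cfr(rep(ps, each = 12), ors) <= 1))
})

test_that("the odds-scale flag applies the ratio on the odds scale", {
  # odds 1 * OR 2 -> odds 2 -> probability 2/3
  expect_equal(derive_post_cfr(0.5, 2, odds_scale = TRUE), 2 / 3)
  # small probabilities: odds and risk scales nearly agree
  expect_equal(derive_post_cfr(0.001, 0.5, odds_scale = TRUE),
               derive_post_cfr(0.001, 0.5), tolerance = 1e-3)
})

test_that("gamma fit matches the method-of-moments oracle", {
  d <- fit_distribution(15.19, 12.91, 17.47, "gamma")
  sd_oracle <- (17.47 - 12.91) / (2 * qnorm(0.975))
  expect_equal(sd_oracle, 1.163, tolerance = 1e-3)
  expect_equal(d$pars$shape, (15.19 / sd_oracle)^2, tolerance = 1e-12)
  expect_equal(d$pars$shape, 170.5, tolerance = 1e-3)
  expect_equal(1 / d$pars$rate * d$pars$shape, 15.19)  # mean
  expect_equal(1 / d$pars$rate, 0.0891, tolerance = 2e-3) # scale
  # central 95% interval reproduces the printed range within 5%
  q <- qgamma(c(0.025, 0.975), shape = d$pars$shape, rate = d$pars$rate)
  expect_equal(q[1], 12.91, tolerance = 0.05)
  expect_equal(q[2], 17.47, tolerance = 0.05)
  # Monte-Carlo mean within 3 MC standard errors of the base value
  set.seed(11)
  x <- dist_draw(d, 1e6)
  expect_lt(abs(mean(x) - 15.19), 3 * sd(x) / sqrt(1e6))
})

test_that("fixed family is a point mass and beta fit is mean-accurate", {
  d <- fit_distribution(3675, family = "fixed")
  expect_true(all(dist_draw(d, 100) == 3675))
  b <- fit_distribution(0.962, 0.818, 0.992, "beta")
  m <- b$pars$shape1 / (b$pars$shape1 + b$pars$shape2)
  expect_equal(m, 0.962, tolerance = 0.01)
  set.seed(12)
  x <- dist_draw(b, 1e6)
  expect_lt(abs(mean(x) - 0.962), 3 * sd(x) / sqrt(1e6))
  expect_true(all(x >= 0 & x <= 1))
})

test_that("lognormal fit pins the arithmetic mean to the base value", {
  d <- fit_distribution(55, 46.41, 62.79, "lognormal")
  expect_equal(exp(d$pars$meanlog + d$pars$sdlog^2 / 2), 55,
               tolerance = 1e-12)
  set.seed(13)
  x <- dist_draw(d, 1e6)
  expect_lt(abs(mean(x) - 55), 3 * sd(x) / sqrt(1e6))
})

test_that("infeasible ranges are rejected with domain errors", {
  expect_error(fit_distribution(10, 10, 10, "gamma"), "degenerate")
  expect_error(fit_distribution(10, -5, 20, "gamma"), "non-negative")
  expect_error(fit_distribution(0.5, 0, 1, "lognormal"), "positive")
  expect_error(fit_distribution(0.5, NA, NA, "beta"), "range")
})

test_that("every PSA sampling distribution has mean equal to its base", {
  params <- ec_parameters()
  dists <- psa_distributions(params)
  pv <- param_values(params)
  set.seed(21)
  for (nm in names(dists)) {
    x <- dist_draw(dists[[nm]], 1e6)
    mc_se <- sd(x) / sqrt(1e6)
    expect_lt(abs(mean(x) - dist_mean(dists[[nm]])), 3 * mc_se + 1e-12)
    if (!nm %in% c("or_pph", "or_asthma")) {
      expect_equal(dist_mean(dists[[nm]]), unname(pv[nm]), tolerance = 1e-9)
    }
  }
})
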