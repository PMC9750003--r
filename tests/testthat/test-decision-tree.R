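params <- ec_parameters()
pv <- param_values(params)

test_that("branch probabilities along published paths multiply through", {
  prof <- condition_profiles(pv)
  rti_only <- prof[prof$condition == "rti", ]
  rti_only$cohort_share <- 1
  tree <- build_tree(rti_only, disability_split(pv), "pre")
  paths <- evaluate_tree(tree, 1)
  amp <- sum(paths$prob[paths$state == "survive_amputation"])
  expect_equal(amp, (1 - 0.0314) * (1 - 0.962) * 0.788, tolerance = 1e-9)
  expect_equal(amp, 0.029005, tolerance = 1e-4)

  pph_only <- prof[prof$condition == "pph", ]
  pph_only$cohort_share <- 1
  post <- build_tree(pph_only, disability_split(pv), "post")
  death <- tree_paths(post)
  expect_equal(death$prob[death$state == "death_48h"], 0.0172 * 0.000335,
               tolerance = 1e-12)
  expect_equal(death$prob[death$state == "death_48h"], 5.762e-06,
               tolerance = 1e-4)
})

test_that("a degenerate disability split sends every survivor home healthy", {
  pv2 <- pv
  pv2["p_no_disability"] <- 1
  tree <- build_tree(condition_profiles(pv2), disability_split(pv2), "pre")
  paths <- evaluate_tree(tree, 1000)
  expect_equal(sum(paths$expected[paths$state %in%
                                    c("survive_amputation",
                                      "survive_neuro")]), 0)
})

test_that("expected terminal counts are conserved and match the oracle", {
  pv2 <- pv
  for (cc in c("rti", "pph", "asthma", "paediatric_pneumonia",
               "paediatric_diarrhoea")) {
    pv2[paste0("share_", cc)] <- 0.2
  }
  for (arm in c("pre", "post")) {
    tree <- build_tree(condition_profiles(pv2), disability_split(pv2), arm)
    paths <- evaluate_tree(tree, 2241)
    expect_equal(sum(paths$expected), 2241, tolerance = 1e-6)
    # independent hand-enumeration of every path probability
    for (cc in unique(paths$condition)) {
      oracle <- 0.2 * oracle_condition_paths(pv2, cc, arm)
      got <- paths[paths$condition == cc, ]
      expect_equal(sum(got$prob[got$state == "death_48h"]),
                   unname(oracle["death_48h"]), tolerance = 1e-9)
      expect_equal(sum(got$prob[got$state == "survive_healthy"]),
                   unname(oracle["survive_healthy"]), tolerance = 1e-9)
      if (cc == "rti") {
        expect_equal(
          got$prob[got$state == "survive_amputation" & got$rehab_flag],
          unname(oracle["amp_rehab"]), tolerance = 1e-9)
        expect_equal(
          got$prob[got$state == "survive_amputation" & !got$rehab_flag],
          unname(oracle["amp_norehab"]), tolerance = 1e-9)
        expect_equal(sum(got$prob[got$state == "survive_neuro"]),
                     unname(oracle["neuro_rehab"] +
                              oracle["neuro_norehab"]), tolerance = 1e-9)
      }
    }
  }
})

test_that("n = 0 yields all-zero expected counts", {
  tree <- build_tree(condition_profiles(pv), disability_split(pv), "pre")
  expect_true(all(evaluate_tree(tree, 0)$expected == 0))
  expect_error(evaluate_tree(tree, -1), ">= 0")
})

test_that("invalid branch probabilities fail construction", {
  pv2 <- pv
  pv2["p_amputation"] <- 0.5  # complement no longer matches p_neuro row
  split <- disability_split(pv2)
  split$p_neuro_given_disabled <- 0.3
  expect_error(build_tree(condition_profiles(pv2), split, "pre"),
               "sum to 1")
})

test_that("shrinking an odds ratio weakly lowers post-arm deaths", {
  deaths <- vapply(c(0.9, 0.6, 0.265, 0.1, 0), function(or) {
    pv2 <- set_param(pv, "or_rti", or)
    tree <- build_tree(condition_profiles(pv2), disability_split(pv2),
                       "post")
    paths <- evaluate_tree(tree, 3994)
    sum(paths$expected[paths$state == "death_48h"])
  }, numeric(1))
  expect_true(all(diff(deaths) <= 1e-12))
})

test_that("microsimulation is seed-deterministic and conserves patients", {
  tree <- build_tree(condition_profiles(pv), disability_split(pv), "post")
  a <- microsimulate(tree, 10000, seed = 7)
  b <- microsimulate(tree, 10000, seed = 7)
  expect_identical(a, b)
  expect_equal(sum(a$count), 10000)
  expect_false(identical(a$count, microsimulate(tree, 10000, 8)$count))
})

test_that("microsimulated counts agree with the analytic rollback", {
  # fair two-branch tree: a condition with a 50% case-fatality rate
  pv2 <- single_condition_pv(params, "pph")
  pv2["cfr_pre_pph"] <- 0.5
  prof <- condition_profiles(pv2)[2, ]
  tree <- build_tree(prof, disability_split(pv2), "pre")
  n <- 1e6
  sim <- microsimulate(tree, n, seed = 9)
  expect_true(all(abs(sim$count - n / 2) <= 3 * sqrt(n * 0.25)))

  # full default tree: every state within 3 binomial sd of expectation
  full <- build_tree(condition_profiles(pv), disability_split(pv), "pre")
  expected <- evaluate_tree(full, n)
  sim <- microsimulate(full, n, seed = 10)
  sd3 <- 3 * sqrt(n * expected$prob * (1 - expected$prob))
  expect_true(all(abs(sim$count - expected$expected) <= sd3 + 1e-9))

  # degenerate tree: single terminal collects everyone
  pv3 <- single_condition_pv(params, "asthma")
  pv3["cfr_pre_asthma"] <- 0
  prof <- condition_profiles(pv3)[3, ]
  sim <- microsimulate(build_tree(prof, disability_split(pv3), "pre"),
                       500, seed = 11)
  expect_equal(sim$count[sim$state == "survive_healthy"], 500)
})

test_that("trees serialise to JSON and DOT", {
  tree <- build_tree(condition_profiles(pv), disability_split(pv), "pre")
  js <- jsonlite::fromJSON(tree_to_json(tree), simplifyVector = FALSE)
  expect_equal(length(js$branches), 5)
  p_root <- vapply(js$branches, function(b) b$p, numeric(1))
  expect_equal(sum(p_root), 1, tolerance = 1e-12)
  dot <- tree_to_dot(tree)
  expect_match(dot, "digraph decision_tree")
  expect_match(dot, "death_48h")
})
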