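# Parameters varied one at a time in the default tornado: every cost,
# disability-split, weight and model-assumption input with a printed range,
# plus the (assumed) road-traffic-injury cohort share.  Effectiveness
# inputs (case-fatality rates, odds ratios) are explored jointly in the
# PSA instead: two of the five printed odds-ratio intervals are degenerate
# (0 to ~1e37) and carry no one-way information.
DSA_DEFAULT_TARGETS <- c(
  "intervention_cost", "annual_income", "rehabilitation_cost",
  "prosthetic_cost", "episode_cost", "p_no_disability", "p_amputation",
  "p_rehab", "weight_amputation", "weight_neuro", "discount_rate",
  "time_horizon", "share_rti"
)

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the full model with each target parameter set to its low
#' and then its high bound, all others at base, and records the ICER per
#' DALY averted at each bound.  Entries are ranked by swing (absolute
#' difference between the two ICERs).  Setting `p_amputation` moves its
#' complement `p_neuro` implicitly (the two are one degree of freedom),
#' and varying `share_rti` renormalises the other cohort shares.
#'
#' @param params `ec_params` object.
#' @param targets Parameter names to vary (default
#'   `DSA_DEFAULT_TARGETS`).  Targets without a range are skipped with a
#'   warning.
#' @return data.frame of class `ec_tornado`: `parameter`, `low`, `high`,
#'   `icer_at_low`, `icer_at_high`, `swing`, sorted by swing descending.
#' @export
tornado <- function(params, targets = DSA_DEFAULT_TARGETS) {
  stopifnot(inherits(params, "ec_params"))
  tab <- params$table
  pv0 <- param_values(params)
  rows <- list()
  for (tg in targets) {
    i <- match(tg, tab$name)
    if (is.na(i)) {
      warning("skipping unknown tornado target: ", tg, call. = FALSE)
      next
    }
    if (is.na(tab$low[i]) || is.na(tab$high[i])) {
      warning("skipping tornado target without a range: ", tg,
              call. = FALSE)
      next
    }
    icers <- vapply(c(tab$low[i], tab$high[i]), function(v) {
      run_base_case(params,
                    pv = set_param(pv0, tg, v))$incremental$icer_per_daly
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = tg, low = tab$low[i], high = tab$high[i],
      icer_at_low = icers[1], icer_at_high = icers[2],
      swing = abs(icers[2] - icers[1]), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing), ]
  rownames(out) <- NULL
  class(out) <- c("ec_tornado", "data.frame")
  out
}

#' Probabilistic sampling distributions for every uncertain parameter
#'
#' Builds the joint sampling design of the probabilistic sensitivity
#' analysis in the documented draw order (`PSA_DRAW_ORDER`): gamma for
#' costs (income fitted from its sub-regional min/max with
#' `sd = (high-low)/4`), beta for probabilities (pre-intervention
#' case-fatality rates use their +/- 2-binomial-SE ranges), mean-matched
#' lognormal for the informative odds ratios, and — for the two conditions
#' whose printed odds-ratio intervals are degenerate (post-partum
#' haemorrhage, asthma) — a Beta(1, (1-m)/m) draw of the post/pre
#' case-fatality ratio with mean `m = OR base` on \[0, 1\], applied to the
#' sampled pre-intervention rate.  The neurological split is the
#' complement of the sampled amputation split, and the discount rate is
#' not sampled (it is a deterministic policy lever, varied in the
#' tornado).
#'
#' @param params `ec_params` object.
#' @return Named list of `ec_dist` objects in draw order; degenerate-OR
#'   entries carry attribute `ratio_of_pre = TRUE`.
#' @export
psa_distributions <- function(params) {
  tab <- params$table
  lookup <- function(name) tab[match(name, tab$name), ]
  dists <- list()
  for (name in PSA_DRAW_ORDER) {
    s <- lookup(name)
    if (is.na(s$name)) stop("parameter missing from table: ", name,
                            call. = FALSE)
    d <- if (s$family == "fixed") {
      fit_distribution(s$base, family = "fixed")
    } else if (s$group == "cost") {
      fit_distribution(s$base, s$low, s$high, "gamma",
                       range_type = if (name == "annual_income") "minmax"
                                    else "ci95")
    } else if (s$group == "odds_ratio") {
      if (s$high > 100) {  # degenerate printed interval
        m <- s$base
        dd <- structure(list(family = "beta",
                             pars = list(shape1 = 1, shape2 = (1 - m) / m,
                                         lower = 0, upper = 1),
                             mean = m, support = c(0, 1)),
                        class = "ec_dist")
        attr(dd, "ratio_of_pre") <- TRUE
        dd
      } else {
        fit_distribution(s$base, s$low, s$high, "lognormal")
      }
    } else if (s$family == "lognormal") {
      fit_distribution(s$base, s$low, s$high, "lognormal")
    } else {
      fit_distribution(s$base, s$low, s$high, "beta")
    }
    dists[[name]] <- d
  }
  dists
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws `n_draws` independent parameter vectors from
#' [psa_distributions()] — one RNG stream, parameters drawn in table
#' order within each iteration, so results are reproducible from the seed
#' alone — and evaluates the full two-arm model on each vector.
#'
#' @param params `ec_params` object.
#' @param n_draws Number of simulations (default 10,000).
#' @param seed Integer seed.
#' @return List of class `ec_psa`: `draws` (data.frame with the sampled
#'   values and per-draw `delta_cost`, `dalys_averted`, `icer_per_daly`)
#'   and `summary` (means, Monte-Carlo standard errors, cost-saving
#'   fraction with a 95% binomial CI, cost-effectiveness-plane quadrant
#'   counts, seed).
#' @export
run_psa <- function(params, n_draws = 10000, seed = 1) {
  stopifnot(inherits(params, "ec_params"), n_draws >= 1)
  dists <- psa_distributions(params)
  pv0 <- param_values(params)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  nm <- names(dists)
  sampled <- matrix(NA_real_, n_draws, length(nm),
                    dimnames = list(NULL, nm))
  delta_cost <- dalys_averted <- numeric(n_draws)
  for (it in seq_len(n_draws)) {
    pv <- pv0
    for (j in seq_along(nm)) {
      # for the degenerate-interval conditions the draw is the post/pre
      # fatality ratio, which plays the odds ratio's multiplicative role
      x <- dist_draw(dists[[j]], 1)
      sampled[it, j] <- x
      pv[nm[j]] <- x
    }
    pv["p_neuro"] <- 1 - pv["p_amputation"]
    res <- run_base_case(params, pv = pv)$incremental
    delta_cost[it] <- res$delta_cost
    dalys_averted[it] <- res$dalys_averted
  }

  draws <- data.frame(draw = seq_len(n_draws), sampled,
                      delta_cost = delta_cost,
                      dalys_averted = dalys_averted,
                      icer_per_daly = ifelse(dalys_averted != 0,
                                             delta_cost / dalys_averted,
                                             NA_real_))
  p_saving <- mean(delta_cost < 0)
  ci <- stats::binom.test(sum(delta_cost < 0), n_draws)$conf.int
  quadrants <- c(
    ne = sum(delta_cost >= 0 & dalys_averted >= 0),
    se = sum(delta_cost < 0 & dalys_averted >= 0),
    sw = sum(delta_cost < 0 & dalys_averted < 0),
    nw = sum(delta_cost >= 0 & dalys_averted < 0))
  summary <- list(
    n_draws = n_draws, seed = seed,
    mean_delta_cost = mean(delta_cost),
    se_delta_cost = stats::sd(delta_cost) / sqrt(n_draws),
    mean_dalys_averted = mean(dalys_averted),
    se_dalys_averted = stats::sd(dalys_averted) / sqrt(n_draws),
    prob_cost_saving = p_saving,
    prob_cost_saving_ci = as.numeric(ci),
    quadrant_counts = as.list(quadrants))
  structure(list(draws = draws, summary = summary), class = "ec_psa")
}

#' @export
print.ec_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<ec_psa> %d draws | mean delta cost $%.0f | mean DALYs averted %.1f | P(cost-saving) %.3f\n",
    s$n_draws, s$mean_delta_cost, s$mean_dalys_averted,
    s$prob_cost_saving))
  invisible(x)
}

#' Scenario analyses
#'
#' Two structural scenarios are implemented:
#' \describe{
#'   \item{proportional_morbidity}{disability among post-arm survivors
#'     rises proportionally to the mortality benefit (a 47% relative
#'     increase: the post-arm disability probability is multiplied by
#'     1.47).}
#'   \item{retraining_every_5y}{staff turnover forces the full toolkit
#'     cost to recur every five years over the horizon (discounted at the
#'     model rate; at a zero rate and 55-year horizon this is 11 renewals
#'     of the deployment cost).}
#' }
#'
#' @param name Scenario name.
#' @param params `ec_params` object.
#' @param morbidity_multiplier Multiplier for the proportional-morbidity
#'   scenario (default 1.47).
#' @return List with `scenario` (`ec_incremental` under the scenario),
#'   `base` (`ec_incremental` at base case), `delta_dalys_averted`,
#'   `delta_cost_change`.
#' @export
scenario <- function(name = c("proportional_morbidity",
                              "retraining_every_5y"),
                     params = ec_parameters(),
                     morbidity_multiplier = 1.47) {
  if (!is.character(name) ||
      !name[1] %in% c("proportional_morbidity", "retraining_every_5y")) {
    stop("unknown scenario '", name[1],
         "'; available: proportional_morbidity, retraining_every_5y",
         call. = FALSE)
  }
  name <- name[1]
  base <- run_base_case(params)$incremental
  opts <- params$options
  if (name == "proportional_morbidity") {
    opts$morbidity_multiplier <- morbidity_multiplier
  } else {
    opts$retraining_every_5y <- TRUE
  }
  alt_params <- ec_parameters(table = params$table, options = opts)
  alt <- run_base_case(alt_params)$incremental
  list(scenario = alt, base = base,
       delta_dalys_averted = alt$dalys_averted - base$dalys_averted,
       delta_cost_change = alt$delta_cost - base$delta_cost)
}
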