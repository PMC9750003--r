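#' @keywords internal
"_PACKAGE"

# Sentinel conditions tracked by the quality-improvement registry.
SENTINEL_CONDITIONS <- c("rti", "pph", "asthma",
                         "paediatric_pneumonia", "paediatric_diarrhoea")

PARAM_FAMILIES <- c("gamma", "beta", "lognormal", "fixed")

# Parameters sampled jointly in the probabilistic sensitivity analysis, in
# the documented draw order (costs, pre-intervention case-fatality rates,
# odds ratios, disability splits, disability weights, time horizon).  The
# discount rate is deliberately absent: it is a policy choice explored in
# the one-way deterministic analysis only.
PSA_DRAW_ORDER <- c(
  "intervention_cost", "annual_income", "rehabilitation_cost",
  "prosthetic_cost", "episode_cost",
  paste0("cfr_pre_", SENTINEL_CONDITIONS),
  paste0("or_", SENTINEL_CONDITIONS),
  "p_no_disability", "p_amputation", "p_rehab",
  "weight_amputation", "weight_neuro",
  "time_horizon"
)

#' Default model parameter table
#'
#' One row per model input: base-case value, uncertainty range and the
#' sampling-distribution family used in the probabilistic sensitivity
#' analysis.  The table bundles every input of the published model:
#' intervention and care costs (2020 USD), 48-hour case-fatality rates for
#' the five sentinel conditions before the intervention, post-intervention
#' odds ratios, the disability split for road-traffic-injury survivors,
#' disability weights, and the model assumptions (discount rate, life
#' expectancy, time horizon, average annual cash income, UGX/USD rate).
#'
#' Ranges for the pre-intervention case-fatality rates are not published;
#' they default to +/- 2 binomial standard errors at the assumed
#' per-condition sample sizes (pre-intervention arm of 2,241 split by the
#' cohort shares) and are used only by the probabilistic analysis.  Cohort
#' shares themselves are not published and default to an assumed mix
#' (road-traffic injury 0.55, post-partum haemorrhage 0.10, asthma 0.08,
#' paediatric pneumonia 0.15, paediatric diarrhoea 0.12); they are flagged
#' as assumptions and can be overridden in the table.
#'
#' @return A data.frame with columns `name`, `base`, `low`, `high`,
#'   `family`, `units`, `group`.  `low`/`high` are `NA` where no range is
#'   defined (fixed inputs).
#' @export
default_parameter_table <- function() {
  shares <- c(rti = 0.55, pph = 0.10, asthma = 0.08,
              paediatric_pneumonia = 0.15, paediatric_diarrhoea = 0.12)
  cfr <- c(rti = 0.0314, pph = 0.0172, asthma = 0.0111,
           paediatric_pneumonia = 0.0632, paediatric_diarrhoea = 0.0267)
  n_pre <- 2241
  se <- sqrt(cfr * (1 - cfr) / (n_pre * shares))
  ages <- c(rti = 26, pph = 26, asthma = 26,
            paediatric_pneumonia = 2, paediatric_diarrhoea = 2)

  row <- function(name, base, low = NA_real_, high = NA_real_,
                  family = "fixed", units = "", group = "") {
    data.frame(name = name, base = base, low = low, high = high,
               family = family, units = units, group = group,
               stringsAsFactors = FALSE)
  }

  rbind(
    row("intervention_cost", 5873.80, 4992.73, 6754.86, "gamma", "USD", "cost"),
    row("annual_income", 1354.68, 469.16, 3054.55, "gamma", "USD/year", "cost"),
    row("rehabilitation_cost", 27.03, 22.97, 31.08, "gamma", "USD/year", "cost"),
    row("prosthetic_cost", 672.50, 400, 945, "gamma", "USD", "cost"),
    row("episode_cost", 15.19, 12.91, 17.47, "gamma", "USD", "cost"),
    do.call(rbind, lapply(SENTINEL_CONDITIONS, function(cc) {
      row(paste0("cfr_pre_", cc), cfr[[cc]],
          max(0, cfr[[cc]] - 2 * se[[cc]]), min(1, cfr[[cc]] + 2 * se[[cc]]),
          "beta", "probability", "cfr_pre")
    })),
    row("or_rti", 0.265, 0.1130, 0.6216, "beta", "ratio", "odds_ratio"),
    row("or_pph", 0.000335, 0, 3.376e37, "beta", "ratio", "odds_ratio"),
    row("or_asthma", 0.00367, 0, 3.661e34, "beta", "ratio", "odds_ratio"),
    row("or_paediatric_pneumonia", 0.423, 0.2392, 0.7481, "beta", "ratio",
        "odds_ratio"),
    row("or_paediatric_diarrhoea", 0.5742, 0.1495, 2.2048, "beta", "ratio",
        "odds_ratio"),
    row("p_no_disability", 0.962, 0.818, 0.992, "beta", "probability",
        "disability"),
    row("p_amputation", 0.788, 0.670, 0.907, "beta", "probability",
        "disability"),
    row("p_neuro", 0.212, 0.179, 0.243, "beta", "probability", "disability"),
    row("p_rehab", 0.115, 0.098, 0.133, "beta", "probability", "disability"),
    row("weight_amputation", 0.275, 0.234, 0.316, "beta", "DALY weight",
        "daly_weight"),
    row("weight_neuro", 0.359, 0.305, 0.413, "beta", "DALY weight",
        "daly_weight"),
    row("discount_rate", 0.035, 0, 0.05, "beta", "fraction/year",
        "assumption"),
    row("time_horizon", 55, 46.41, 62.79, "lognormal", "years", "assumption"),
    row("life_expectancy", 68.6, family = "fixed", units = "years",
        group = "assumption"),
    row("fx_rate", 3675, family = "fixed", units = "UGX/USD",
        group = "assumption"),
    row("startup_cost", 1683, family = "fixed", units = "USD",
        group = "intervention_component"),
    row("bec_training_cost", 3515, family = "fixed", units = "USD",
        group = "intervention_component"),
    row("triage_tool_cost", 172, family = "fixed", units = "USD",
        group = "intervention_component"),
    row("checklist_tool_cost", 503, family = "fixed", units = "USD",
        group = "intervention_component"),
    do.call(rbind, lapply(SENTINEL_CONDITIONS, function(cc) {
      # RTI share carries a +/-25% relative range so the one-way DSA can
      # probe the (unpublished) condition mix; other shares renormalise.
      if (cc == "rti") {
        row(paste0("share_", cc), shares[[cc]],
            0.75 * shares[[cc]], 1.25 * shares[[cc]],
            "fixed", "probability", "cohort_share")
      } else {
        row(paste0("share_", cc), shares[[cc]], family = "fixed",
            units = "probability", group = "cohort_share")
      }
    })),
    do.call(rbind, lapply(SENTINEL_CONDITIONS, function(cc) {
      row(paste0("age_", cc), ages[[cc]], family = "fixed", units = "years",
          group = "median_age")
    }))
  )
}

#' Assemble a validated parameter set
#'
#' @param table Parameter table as returned by [default_parameter_table()]
#'   (or loaded from file); defaults to the bundled base case.
#' @param options Named list overriding run options; see Details.
#'
#' @details Run options (each default is the model's reference choice):
#' \describe{
#'   \item{or_on_odds_scale}{`FALSE` — odds ratios are applied
#'     multiplicatively on the probability scale, as the source model
#'     states; `TRUE` switches to the statistically orthodox odds-scale
#'     conversion.}
#'   \item{working_age_floor}{15 — income cannot be lost before this age;
#'     set to 0 for a naive human-capital reading.}
#'   \item{prosthetic_anchor_year}{0 — first prosthetic at the year of
#'     injury, renewals every 5 years within the horizon.}
#'   \item{morbidity_multiplier}{1 — multiplier on the post-arm disability
#'     probability (the proportional-morbidity scenario sets 1.47).}
#'   \item{retraining_every_5y}{`FALSE` — repeat the full intervention cost
#'     every five years over the horizon.}
#'   \item{n_patients}{3994 — annual modelled cohort (pre- plus
#'     post-intervention registry arms, 2,241 + 1,753).}
#'   \item{n_pre, n_post}{registry arm sizes used by the cohort generator.}
#' }
#'
#' @return An object of class `ec_params`.
#' @export
ec_parameters <- function(table = default_parameter_table(), options = list()) {
  stopifnot(is.data.frame(table))
  errs <- validate_parameter_table(table)
  if (length(errs)) {
    stop("invalid parameter table:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  opts <- list(
    or_on_odds_scale = FALSE,
    working_age_floor = 15,
    prosthetic_anchor_year = 0,
    morbidity_multiplier = 1,
    retraining_every_5y = FALSE,
    n_patients = 3994, n_pre = 2241, n_post = 1753
  )
  opts[names(options)] <- options
  structure(list(table = table, options = opts), class = "ec_params")
}

#' @export
print.ec_params <- function(x, ...) {
  cat("<ec_params>", nrow(x$table), "parameters;",
      length(SENTINEL_CONDITIONS), "sentinel conditions\n")
  invisible(x)
}

#' Validate a parameter table, collecting every violation
#'
#' @param table Candidate parameter table.
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_parameter_table <- function(table) {
  errs <- character()
  need_cols <- c("name", "base", "low", "high", "family", "units", "group")
  missing_cols <- setdiff(need_cols, names(table))
  if (length(missing_cols)) {
    return(paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  }
  required <- default_parameter_table()$name
  absent <- setdiff(required, table$name)
  for (p in absent) errs <- c(errs, paste0("missing parameter: ", p))
  dup <- unique(table$name[duplicated(table$name)])
  for (p in dup) errs <- c(errs, paste0("duplicated parameter: ", p))

  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    if (!r$family %in% PARAM_FAMILIES) {
      errs <- c(errs, sprintf("%s: unknown family '%s'", r$name, r$family))
    }
    has_range <- !is.na(r$low) && !is.na(r$high)
    if (has_range && !(r$low <= r$base && r$base <= r$high)) {
      errs <- c(errs, sprintf(
        "%s: base %.6g outside range [%.6g, %.6g]", r$name, r$base, r$low,
        r$high))
    }
    if (r$group %in% c("cfr_pre", "disability", "cohort_share") ||
        identical(r$units, "probability")) {
      if (is.na(r$base) || r$base < 0 || r$base > 1) {
        errs <- c(errs, sprintf("%s: probability %.6g outside [0, 1]",
                                r$name, r$base))
      }
    }
    if (identical(r$family, "gamma") && (is.na(r$base) || r$base <= 0)) {
      errs <- c(errs, sprintf("%s: gamma family requires base > 0", r$name))
    }
  }

  shares <- table$base[match(paste0("share_", SENTINEL_CONDITIONS),
                             table$name)]
  if (!anyNA(shares)) {
    if (any(shares < 0 | shares > 1)) {
      errs <- c(errs, "cohort shares must lie in [0, 1]")
    }
    if (all(shares == 0)) {
      errs <- c(errs, "all cohort shares are zero")
    } else if (abs(sum(shares) - 1) > 1e-9) {
      errs <- c(errs, sprintf("cohort shares sum to %.9f, not 1", sum(shares)))
    }
  }
  amp <- table$base[match("p_amputation", table$name)]
  neu <- table$base[match("p_neuro", table$name)]
  if (!is.na(amp) && !is.na(neu) && abs(amp + neu - 1) > 1e-9) {
    errs <- c(errs, "p_amputation + p_neuro must equal 1")
  }
  dr <- table$base[match("discount_rate", table$name)]
  if (!is.na(dr) && (dr < 0 || dr > 0.05)) {
    errs <- c(errs, "discount_rate outside the supported 0-0.05 range")
  }
  errs
}

#' Load a parameter table from CSV or JSON
#'
#' The file must carry the documented schema: columns `name`, `base`,
#' `low`, `high`, `family`, `units`, `group` (CSV), or a JSON array of
#' objects with the same fields.  All validation violations are reported at
#' once.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param options Run options forwarded to [ec_parameters()].
#' @return An `ec_params` object.
#' @export
load_parameter_table <- function(path, options = list()) {
  if (!file.exists(path)) stop("parameter table not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  tab <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    stop("unsupported parameter-table format: .", ext, call. = FALSE)
  )
  for (col in c("base", "low", "high")) {
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  ec_parameters(table = tab, options = options)
}

#' Write a parameter table to CSV or JSON
#'
#' Inverse of [load_parameter_table()]; a write/read round trip preserves
#' every field bit-for-bit.
#'
#' @param params `ec_params` object.
#' @param path Destination `.csv` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  stopifnot(inherits(params, "ec_params"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- params$table
    for (col in c("base", "low", "high")) {
      # 17 significant digits: doubles survive the text round trip exactly
      tab[[col]] <- ifelse(is.na(tab[[col]]), "",
                           sprintf("%.17g", tab[[col]]))
    }
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(params$table, path, dataframe = "rows", na = "null",
                         digits = I(17), auto_unbox = FALSE)
  } else {
    stop("unsupported parameter-table format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Path to the bundled default parameter table
#'
#' The packaged CSV reproducing every model input (the base case shipped
#' by [default_parameter_table()]).
#'
#' @return File path of the installed CSV.
#' @export
ec_parameter_file <- function() {
  system.file("extdata", "parameter_table.csv", package = "ectoolkit",
              mustWork = TRUE)
}

#' Base-case parameter values as a named vector
#'
#' @param params `ec_params` object.
#' @return Named numeric vector of base values, one per table row.
#' @export
param_values <- function(params) {
  stopifnot(inherits(params, "ec_params"))
  stats::setNames(params$table$base, params$table$name)
}

#' Override one parameter value, renormalising cohort shares
#'
#' Cohort shares must sum to one, so setting `share_<condition>` rescales
#' the remaining four shares proportionally; every other name is a plain
#' assignment.
#'
#' @param pv Named numeric vector from [param_values()].
#' @param name Parameter name.
#' @param value New value.
#' @return Modified copy of `pv`.
#' @export
set_param <- function(pv, name, value) {
  if (!name %in% names(pv)) stop("unknown parameter: ", name, call. = FALSE)
  if (grepl("^share_", name)) {
    others <- setdiff(paste0("share_", SENTINEL_CONDITIONS), name)
    rest <- sum(pv[others])
    if (rest <= 0) stop("cannot renormalise: other shares are zero",
                        call. = FALSE)
    pv[others] <- pv[others] * (1 - value) / rest
  }
  pv[name] <- value
  pv
}

#' Per-condition epidemiology profiles
#'
#' Assembles one row per sentinel condition (pre-intervention 48-hour
#' case-fatality rate, post-intervention odds ratio, median age, treatment
#' cost per episode, cohort share) from a parameter-value vector.
#'
#' @param pv Named values from [param_values()] (possibly perturbed).
#' @return data.frame with one row per sentinel condition.
#' @export
condition_profiles <- function(pv) {
  data.frame(
    condition = SENTINEL_CONDITIONS,
    pre_cfr = unname(pv[paste0("cfr_pre_", SENTINEL_CONDITIONS)]),
    odds_ratio_post = unname(pv[paste0("or_", SENTINEL_CONDITIONS)]),
    median_age = unname(pv[paste0("age_", SENTINEL_CONDITIONS)]),
    episode_cost = unname(rep(pv["episode_cost"],
                              length(SENTINEL_CONDITIONS))),
    cohort_share = unname(pv[paste0("share_", SENTINEL_CONDITIONS)]),
    stringsAsFactors = FALSE
  )
}

#' Disability split for road-traffic-injury survivors
#'
#' @param pv Named values from [param_values()].
#' @return List with elements `p_no_disability`,
#'   `p_amputation_given_disabled`, `p_neuro_given_disabled`, `p_rehab`,
#'   `weight_amputation`, `weight_neuro`.  The neurological share is
#'   derived as the complement of the amputation share so the two always
#'   sum to one, also under sampling.
#' @export
disability_split <- function(pv) {
  list(
    p_no_disability = unname(pv["p_no_disability"]),
    p_amputation_given_disabled = unname(pv["p_amputation"]),
    p_neuro_given_disabled = 1 - unname(pv["p_amputation"]),
    p_rehab = unname(pv["p_rehab"]),
    weight_amputation = unname(pv["weight_amputation"]),
    weight_neuro = unname(pv["weight_neuro"])
  )
}

#' Model assumptions block
#'
#' @param pv Named values from [param_values()].
#' @return List with `discount_rate`, `life_expectancy`, `time_horizon`,
#'   `annual_income`, `fx_rate`.
#' @export
model_assumptions <- function(pv) {
  list(
    discount_rate = unname(pv["discount_rate"]),
    life_expectancy = unname(pv["life_expectancy"]),
    time_horizon = unname(pv["time_horizon"]),
    annual_income = unname(pv["annual_income"]),
    fx_rate = unname(pv["fx_rate"])
  )
}

#' Derive the post-intervention case-fatality probability
#'
#' The source model derives post-intervention transition probabilities by
#' multiplying the pre-intervention 48-hour case-fatality probability by
#' the reported odds ratio; that multiplicative (risk-scale) reading is the
#' default here.  The statistically orthodox odds-scale conversion
#' (`odds_scale = TRUE`) transforms to odds, applies the ratio, and
#' back-transforms.
#'
#' @param pre_cfr Pre-intervention case-fatality probability in \[0, 1\].
#' @param odds_ratio Non-negative odds ratio.
#' @param odds_scale Apply the ratio on the odds scale instead of the
#'   probability scale (default `FALSE`).
#' @return Post-intervention probability, capped at 1.  Vectorised.
#' @export
#' @examples
#' derive_post_cfr(0.0314, 0.265)  # 0.0083210
derive_post_cfr <- function(pre_cfr, odds_ratio, odds_scale = FALSE) {
  if (any(pre_cfr < 0 | pre_cfr > 1)) {
    stop("pre_cfr must lie in [0, 1]", call. = FALSE)
  }
  if (any(odds_ratio < 0)) stop("odds_ratio must be >= 0", call. = FALSE)
  if (odds_scale) {
    odds <- pre_cfr / (1 - pre_cfr) * odds_ratio
    p <- ifelse(is.infinite(odds), 1, odds / (1 + odds))
    ifelse(pre_cfr == 1, 1, p)
  } else {
    pmin(pre_cfr * odds_ratio, 1)
  }
}

#' Fit a sampling distribution to a base value and range
#'
#' Ranges are interpreted as central 95% intervals unless
#' `range_type = "minmax"` (observed extremes, as for the sub-regional
#' income range), in which case the pragmatic standard deviation
#' `(high - low)/4` is used instead of `(high - low)/3.92`.  Every family
#' is moment-matched so the fitted mean equals `base`:
#' \describe{
#'   \item{gamma}{shape `(base/sd)^2`, rate `base/sd^2`.}
#'   \item{beta}{mean/variance match on the (optionally rescaled) unit
#'     interval; `lower`/`upper` give the support (e.g. 0-0.05 for the
#'     discount rate, whose printed range is a support, not a CI).}
#'   \item{lognormal}{`sdlog = log(high/low)/3.92` (the printed odds-ratio
#'     intervals are geometric), `meanlog = log(base) - sdlog^2/2` so the
#'     arithmetic mean is `base`.}
#'   \item{fixed}{degenerate point mass at `base`.}
#' }
#'
#' @param base Base-case value (fitted mean).
#' @param low,high Range endpoints (ignored for `fixed`).
#' @param family One of `"gamma"`, `"beta"`, `"lognormal"`, `"fixed"`.
#' @param range_type `"ci95"` (default) or `"minmax"`.
#' @param lower,upper Support bounds for the beta family (defaults 0, 1).
#' @return An object of class `ec_dist` with elements `family`, `pars`,
#'   `mean`, `support`.
#' @export
fit_distribution <- function(base, low = NA, high = NA,
                             family = c("gamma", "beta", "lognormal", "fixed"),
                             range_type = c("ci95", "minmax"),
                             lower = 0, upper = 1) {
  family <- match.arg(family)
  range_type <- match.arg(range_type)
  if (family == "fixed") {
    return(structure(list(family = "fixed", pars = list(value = base),
                          mean = base, support = c(base, base)),
                     class = "ec_dist"))
  }
  if (is.na(low) || is.na(high)) {
    stop("family '", family, "' requires a range", call. = FALSE)
  }
  if (high <= low) {
    stop("degenerate range [", low, ", ", high, "] for family '", family,
         "'", call. = FALSE)
  }
  divisor <- if (range_type == "ci95") 2 * stats::qnorm(0.975) else 4
  sd <- (high - low) / divisor
  if (family == "gamma") {
    if (base <= 0 || low < 0) {
      stop("gamma family requires positive base and non-negative low",
           call. = FALSE)
    }
    shape <- (base / sd)^2
    rate <- base / sd^2
    dist <- list(family = "gamma", pars = list(shape = shape, rate = rate),
                 mean = base, support = c(0, Inf))
  } else if (family == "beta") {
    width <- upper - lower
    m <- (base - lower) / width
    s <- sd / width
    if (m <= 0 || m >= 1) {
      stop("beta family requires base strictly inside its support",
           call. = FALSE)
    }
    nu <- m * (1 - m) / s^2 - 1
    if (nu <= 0) {
      stop("beta range too wide for a proper moment-matched fit",
           call. = FALSE)
    }
    dist <- list(family = "beta",
                 pars = list(shape1 = m * nu, shape2 = (1 - m) * nu,
                             lower = lower, upper = upper),
                 mean = base, support = c(lower, upper))
  } else { # lognormal
    if (base <= 0 || low <= 0) {
      stop("lognormal family requires positive base and low", call. = FALSE)
    }
    sdlog <- log(high / low) / (2 * stats::qnorm(0.975))
    meanlog <- log(base) - sdlog^2 / 2
    dist <- list(family = "lognormal",
                 pars = list(meanlog = meanlog, sdlog = sdlog),
                 mean = base, support = c(0, Inf))
  }
  structure(dist, class = "ec_dist")
}

#' Draw from a fitted sampling distribution
#'
#' @param dist `ec_dist` object from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
dist_draw <- function(dist, n) {
  stopifnot(inherits(dist, "ec_dist"))
  switch(dist$family,
    fixed = rep(dist$pars$value, n),
    gamma = stats::rgamma(n, shape = dist$pars$shape, rate = dist$pars$rate),
    beta = dist$pars$lower + (dist$pars$upper - dist$pars$lower) *
      stats::rbeta(n, dist$pars$shape1, dist$pars$shape2),
    lognormal = stats::rlnorm(n, dist$pars$meanlog, dist$pars$sdlog)
  )
}

#' @export
print.ec_dist <- function(x, ...) {
  cat("<ec_dist>", x$family, "mean", signif(x$mean, 6), "\n")
  invisible(x)
}

#' Mean of a fitted sampling distribution
#' @param dist `ec_dist` object.
#' @return The analytic mean.
#' @export
dist_mean <- function(dist) dist$mean
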