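# Closed-form continuous annuity: the independent discounting oracle.
annuity_oracle <- function(duration, rate) {
  if (rate == 0) duration else (1 - (1 + rate)^(-duration)) / rate
}

# Single-condition parameter set: every cohort share moved onto `cond`.
single_condition_pv <- function(params, cond) {
  pv <- param_values(params)
  for (cc in ectoolkit:::SENTINEL_CONDITIONS) {
    pv[paste0("share_", cc)] <- as.numeric(cc == cond)
  }
  pv
}

# Hand-enumerated terminal probabilities of one condition's subtree at
# parameter values pv (independent arithmetic, no tree code involved).
oracle_condition_paths <- function(pv, cond, arm) {
  cfr <- pv[[paste0("cfr_pre_", cond)]]
  if (arm == "post") cfr <- min(1, cfr * pv[[paste0("or_", cond)]])
  if (cond != "rti") {
    return(c(death_48h = cfr, survive_healthy = 1 - cfr))
  }
  p_dis <- 1 - pv[["p_no_disability"]]
  p_amp <- pv[["p_amputation"]]
  p_neu <- 1 - p_amp
  rehab_in_amp <- min(1, pv[["p_rehab"]] / p_amp)
  rehab_in_neu <- max(0, pv[["p_rehab"]] - p_amp) / p_neu
  c(death_48h = cfr,
    survive_healthy = (1 - cfr) * (1 - p_dis),
    amp_rehab = (1 - cfr) * p_dis * p_amp * rehab_in_amp,
    amp_norehab = (1 - cfr) * p_dis * p_amp * (1 - rehab_in_amp),
    neuro_rehab = (1 - cfr) * p_dis * p_neu * rehab_in_neu,
    neuro_norehab = (1 - cfr) * p_dis * p_neu * (1 - rehab_in_neu))
}

# A fabricated arm (costs and burden only), for incremental() arithmetic.
fake_arm <- function(cost_total, dalys, yll) {
  list(cost = list(total = cost_total),
       health = list(dalys = dalys, yll = yll))
}
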