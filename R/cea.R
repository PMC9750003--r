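#' Incremental cost-effectiveness comparison
#'
#' Differences are computed toolkit minus no-toolkit: `delta_cost` is the
#' incremental societal cost, `dalys_averted` and `lys` the health gains
#' (comparator burden minus toolkit burden).  The ICER is
#' `delta_cost / dalys_averted` when DALYs averted are non-zero, otherwise
#' tagged `"undefined"`.  A strategy that is cheaper and more effective is
#' tagged `"dominant"`; its (negative) ICER is reported alongside the tag,
#' as negative ICERs are conventionally shown but are not rankable.  More
#' costly and less effective is `"dominated"`.
#'
#' @param arm_no_toolkit,arm_toolkit Either `ec_arm` objects from
#'   [evaluate_strategy()] or bare lists with `cost` (`$total`) and
#'   `health` (`$dalys`, `$yll`).
#' @param wtp Willingness-to-pay thresholds (USD/DALY averted) at which
#'   net-monetary-benefit verdicts are evaluated.
#' @return List of class `ec_incremental`: `delta_cost`, `dalys_averted`,
#'   `lys`, `delta_yll`, `icer_per_daly`, `icer_per_lys`, `tag`
#'   (`"dominant"`, `"dominated"`, `"undefined"`, or `"tradeoff"`),
#'   `verdicts` (named logical per threshold).
#' @export
incremental <- function(arm_no_toolkit, arm_toolkit, wtp = c(11, 289)) {
  c0 <- arm_no_toolkit$cost$total
  c1 <- arm_toolkit$cost$total
  e0 <- arm_no_toolkit$health$dalys
  e1 <- arm_toolkit$health$dalys
  y0 <- arm_no_toolkit$health$yll
  y1 <- arm_toolkit$health$yll

  delta_cost <- c1 - c0
  dalys_averted <- e0 - e1
  delta_yll <- y0 - y1

  icer <- if (dalys_averted != 0) delta_cost / dalys_averted else NA_real_
  icer_lys <- if (delta_yll != 0) delta_cost / delta_yll else NA_real_
  tag <- if (dalys_averted == 0) {
    if (delta_cost == 0) "indifferent" else "undefined"
  } else if (delta_cost < 0 && dalys_averted > 0) {
    "dominant"
  } else if (delta_cost > 0 && dalys_averted < 0) {
    "dominated"
  } else {
    "tradeoff"
  }

  res <- structure(list(delta_cost = delta_cost,
                        dalys_averted = dalys_averted,
                        lys = delta_yll, delta_yll = delta_yll,
                        icer_per_daly = icer, icer_per_lys = icer_lys,
                        tag = tag),
                   class = "ec_incremental")
  res$verdicts <- wtp_verdicts(res, wtp)
  res
}

#' Willingness-to-pay verdicts via net monetary benefit
#'
#' A result is cost-effective at threshold `lambda` iff
#' `dalys_averted * lambda - delta_cost >= 0`.  Dominant results are
#' cost-effective at every non-negative threshold; the degenerate
#' zero-difference case is cost-effective at all thresholds by convention
#' (tag `"indifferent"`).
#'
#' @param result `ec_incremental` (or list with `delta_cost`,
#'   `dalys_averted`).
#' @param thresholds Positive USD/DALY thresholds.
#' @return Named logical vector, one verdict per threshold.
#' @export
wtp_verdicts <- function(result, thresholds) {
  if (any(thresholds < 0)) stop("thresholds must be >= 0", call. = FALSE)
  nmb <- result$dalys_averted * thresholds - result$delta_cost
  stats::setNames(nmb >= 0, paste0("wtp_", thresholds))
}

#' @export
print.ec_incremental <- function(x, ...) {
  cat(sprintf(
    "<ec_incremental> delta cost $%.0f | DALYs averted %.1f | ICER %s [%s]\n",
    x$delta_cost, x$dalys_averted,
    if (is.na(x$icer_per_daly)) "undefined"
    else sprintf("$%.2f/DALY", x$icer_per_daly),
    x$tag))
  invisible(x)
}

#' Arm-level and incremental results as a table
#'
#' Mirrors the published presentation: one row per strategy plus a
#' difference row, with costs, DALYs, YLL and the two ICERs.
#'
#' @param base List from [run_base_case()].
#' @return data.frame with rows `no_toolkit`, `toolkit`, `difference`.
#' @export
cea_table <- function(base) {
  inc <- base$incremental
  data.frame(
    strategy = c("no_toolkit", "toolkit", "difference"),
    cost_usd = c(base$no_toolkit$cost$total, base$toolkit$cost$total,
                 inc$delta_cost),
    dalys = c(base$no_toolkit$health$dalys, base$toolkit$health$dalys,
              inc$dalys_averted),
    yll = c(base$no_toolkit$health$yll, base$toolkit$health$yll,
            inc$delta_yll),
    icer_per_daly = c(NA, NA, inc$icer_per_daly),
    icer_per_lys = c(NA, NA, inc$icer_per_lys),
    tag = c("", "", inc$tag),
    stringsAsFactors = FALSE
  )
}
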