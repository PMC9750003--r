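#' Simulate a patient-level quality-improvement registry cohort
#'
#' Generates the statistical structure the decision model assumes: each
#' patient is assigned one of the five sentinel conditions with probability
#' equal to its cohort share; 48-hour death is Bernoulli at the
#' condition-specific case-fatality rate, with the post-intervention arm's
#' rate derived from the odds ratio via [derive_post_cfr()].  Ages are
#' point masses at the condition median (the model only uses medians); a
#' dispersion `age_sd` exists for stress tests and draws a normal truncated
#' at zero.
#'
#' @param params `ec_params` object (or a perturbed value vector via `pv`).
#' @param n_pre,n_post Arm sizes (defaults: registry sizes 2,241 and 1,753).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param age_sd Optional age dispersion in years (default 0).
#' @param pv Optional named parameter-value vector overriding
#'   `param_values(params)`.
#' @return A data.frame of class `ec_cohort` with columns `arm`
#'   (`"pre"`/`"post"`), `condition`, `died_48h` (logical), `age`; the seed
#'   and generator settings are attached as attributes.
#' @export
simulate_cohort <- function(params, n_pre = NULL, n_post = NULL, seed = 1,
                            age_sd = 0, pv = NULL) {
  stopifnot(inherits(params, "ec_params"))
  if (is.null(pv)) pv <- param_values(params)
  n_pre <- if (is.null(n_pre)) params$options$n_pre else n_pre
  n_post <- if (is.null(n_post)) params$options$n_post else n_post
  if (n_pre <= 0 || n_post <= 0) stop("arm sizes must be positive",
                                      call. = FALSE)
  prof <- condition_profiles(pv)
  if (all(prof$cohort_share == 0)) {
    stop("all cohort shares are zero", call. = FALSE)
  }
  post_cfr <- derive_post_cfr(prof$pre_cfr, prof$odds_ratio_post,
                              params$options$or_on_odds_scale)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draw_arm <- function(n, arm, cfr) {
    idx <- sample.int(nrow(prof), n, replace = TRUE,
                      prob = prof$cohort_share)
    died <- stats::rbinom(n, 1L, cfr[idx]) == 1L
    age <- prof$median_age[idx]
    if (age_sd > 0) age <- pmax(0, stats::rnorm(n, age, age_sd))
    data.frame(arm = arm, condition = prof$condition[idx],
               died_48h = died, age = age, stringsAsFactors = FALSE)
  }
  cohort <- rbind(draw_arm(n_pre, "pre", prof$pre_cfr),
                  draw_arm(n_post, "post", post_cfr))
  structure(cohort,
            seed = seed, n_pre = n_pre, n_post = n_post, age_sd = age_sd,
            class = c("ec_cohort", "data.frame"))
}

#' Estimate case-fatality rates and odds ratios from a cohort
#'
#' For each sentinel condition present, tabulates the 2x2 death table by
#' arm and returns the pre- and post-arm case-fatality rates and the odds
#' ratio `(d_post/s_post)/(d_pre/s_pre)` with a Woolf (logit-scale) 95%
#' confidence interval `exp(log OR +/- 1.96 * sqrt(1/d_pre + 1/s_pre +
#' 1/d_post + 1/s_post))`.  Any zero cell triggers the 0.5 continuity
#' correction applied to all four cells of that condition's table.
#'
#' @param cohort data.frame with columns `arm`, `condition`, `died_48h`.
#' @return data.frame with one row per condition: `condition`, `n_pre`,
#'   `n_post`, `cfr_pre`, `cfr_post`, `odds_ratio`, `or_low`, `or_high`,
#'   `continuity_corrected`.
#' @export
estimate_rates <- function(cohort) {
  stopifnot(all(c("arm", "condition", "died_48h") %in% names(cohort)))
  conds <- sort(unique(cohort$condition))
  out <- lapply(conds, function(cc) {
    sub <- cohort[cohort$condition == cc, ]
    pre <- sub[sub$arm == "pre", ]
    post <- sub[sub$arm == "post", ]
    if (nrow(pre) == 0 || nrow(post) == 0) {
      stop("condition '", cc, "' is absent from the ",
           if (nrow(pre) == 0) "pre" else "post", " arm", call. = FALSE)
    }
    d1 <- sum(pre$died_48h); s1 <- nrow(pre) - d1
    d2 <- sum(post$died_48h); s2 <- nrow(post) - d2
    cc_applied <- any(c(d1, s1, d2, s2) == 0)
    cells <- c(d1, s1, d2, s2) + if (cc_applied) 0.5 else 0
    or <- (cells[3] / cells[4]) / (cells[1] / cells[2])
    se <- sqrt(sum(1 / cells))
    data.frame(condition = cc, n_pre = nrow(pre), n_post = nrow(post),
               cfr_pre = d1 / nrow(pre), cfr_post = d2 / nrow(post),
               odds_ratio = or,
               or_low = or * exp(-stats::qnorm(0.975) * se),
               or_high = or * exp(stats::qnorm(0.975) * se),
               continuity_corrected = cc_applied,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a cohort to CSV with a JSON provenance sidecar
#'
#' @param cohort `ec_cohort` from [simulate_cohort()].
#' @param path Destination CSV path; the sidecar is written next to it as
#'   `<path>.json` and echoes the generator settings and seed.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  meta <- list(seed = attr(cohort, "seed"),
               n_pre = attr(cohort, "n_pre"),
               n_post = attr(cohort, "n_post"),
               age_sd = attr(cohort, "age_sd"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV path.
#' @return `ec_cohort` data.frame (attributes restored from the sidecar if
#'   present).
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort$died_48h <- as.logical(cohort$died_48h)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    for (f in names(meta)) attr(cohort, f) <- meta[[f]]
  }
  class(cohort) <- c("ec_cohort", "data.frame")
  cohort
}
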