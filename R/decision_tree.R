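TERMINAL_STATES <- c("death_48h", "survive_healthy", "survive_amputation",
                     "survive_neuro")

chance_node <- function(label, probs, children) {
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("branch probabilities of '", label, "' sum to ",
         format(sum(probs), digits = 12), ", not 1", call. = FALSE)
  }
  if (any(probs < 0 | probs > 1)) {
    stop("branch probability outside [0, 1] at '", label, "'", call. = FALSE)
  }
  structure(list(label = label,
                 branches = Map(function(p, ch) list(p = p, node = ch),
                                probs, children)),
            class = "ec_node")
}

terminal_node <- function(state, condition, age, rehab_flag = FALSE) {
  stopifnot(state %in% TERMINAL_STATES)
  if (rehab_flag && !state %in% c("survive_amputation", "survive_neuro")) {
    stop("rehab_flag is only valid for disabled survivors", call. = FALSE)
  }
  structure(list(label = state, state = state, condition = condition,
                 age_at_event = age, rehab_flag = rehab_flag),
            class = c("ec_terminal", "ec_node"))
}

#' Build the two-arm decision tree
#'
#' Encodes the model structure: a chance node over the five sentinel
#' conditions (cohort shares), then 48-hour death versus survival at the
#' arm's case-fatality rate.  Survivors of every condition except
#' road-traffic injury terminate in full health.  RTI survivors split into
#' no-disability versus disabled; the disabled split into amputation and
#' neurological-deficit branches, and rehabilitation need is assigned to a
#' fraction `p_rehab` of all disabled survivors, filling the amputation
#' branch first (spilling into the neurological branch only if
#' `p_rehab` exceeds the amputation share).
#'
#' @param profiles Condition profiles from [condition_profiles()].
#' @param split Disability split from [disability_split()].
#' @param arm `"pre"` (no toolkit) or `"post"` (toolkit); the post arm uses
#'   [derive_post_cfr()] probabilities.
#' @param odds_scale Passed to [derive_post_cfr()].
#' @param morbidity_multiplier Multiplier on the post-arm disability
#'   probability `1 - p_no_disability` (proportional-morbidity scenario).
#' @return Root `ec_node`.
#' @export
build_tree <- function(profiles, split, arm = c("pre", "post"),
                       odds_scale = FALSE, morbidity_multiplier = 1) {
  arm <- match.arg(arm)
  p_dis <- 1 - split$p_no_disability
  if (arm == "post") p_dis <- min(1, p_dis * morbidity_multiplier)
  p_amp <- split$p_amputation_given_disabled
  p_neu <- split$p_neuro_given_disabled
  if (abs(p_amp + p_neu - 1) > 1e-9) {
    stop("disability branches must sum to 1", call. = FALSE)
  }
  # Rehab need covers a fraction p_rehab of disabled survivors, assigned
  # within the amputation branch first.
  rehab_amp <- if (p_amp > 0) min(1, split$p_rehab / p_amp) else 0
  rehab_neu <- if (p_neu > 0) {
    max(0, split$p_rehab - p_amp) / p_neu
  } else 0

  subtree <- function(row) {
    cfr <- if (arm == "post") {
      derive_post_cfr(row$pre_cfr, row$odds_ratio_post, odds_scale)
    } else {
      row$pre_cfr
    }
    death <- terminal_node("death_48h", row$condition, row$median_age)
    survive <- if (row$condition == "rti") {
      amp_children <- list(
        terminal_node("survive_amputation", row$condition, row$median_age,
                      rehab_flag = TRUE),
        terminal_node("survive_amputation", row$condition, row$median_age,
                      rehab_flag = FALSE))
      amp <- chance_node("rehab need (amputation)",
                         c(rehab_amp, 1 - rehab_amp), amp_children)
      neu_children <- list(
        terminal_node("survive_neuro", row$condition, row$median_age,
                      rehab_flag = TRUE),
        terminal_node("survive_neuro", row$condition, row$median_age,
                      rehab_flag = FALSE))
      neu <- chance_node("rehab need (neurological)",
                         c(rehab_neu, 1 - rehab_neu), neu_children)
      disabled <- chance_node("disability type", c(p_amp, p_neu),
                              list(amp, neu))
      chance_node("disability", c(1 - p_dis, p_dis),
                  list(terminal_node("survive_healthy", row$condition,
                                     row$median_age),
                       disabled))
    } else {
      terminal_node("survive_healthy", row$condition, row$median_age)
    }
    chance_node(paste0("48h outcome (", row$condition, ")"),
                c(cfr, 1 - cfr), list(death, survive))
  }

  children <- lapply(seq_len(nrow(profiles)),
                     function(i) subtree(profiles[i, ]))
  chance_node(paste0("sentinel condition [", arm, " arm]"),
              profiles$cohort_share, children)
}

#' Terminal-state table of a tree
#'
#' Walks every root-to-leaf path, multiplying branch probabilities.
#'
#' @param root `ec_node`.
#' @return data.frame with one row per leaf: `condition`, `state`,
#'   `rehab_flag`, `age_at_event`, `prob`.
#' @export
tree_paths <- function(root) {
  condition <- state <- character()
  rehab <- logical()
  age <- prob <- numeric()
  walk <- function(node, p) {
    if (inherits(node, "ec_terminal")) {
      condition[length(condition) + 1L] <<- node$condition
      state[length(state) + 1L] <<- node$state
      rehab[length(rehab) + 1L] <<- node$rehab_flag
      age[length(age) + 1L] <<- node$age_at_event
      prob[length(prob) + 1L] <<- p
    } else {
      for (b in node$branches) walk(b$node, p * b$p)
    }
  }
  walk(root, 1)
  data.frame(condition = condition, state = state, rehab_flag = rehab,
             age_at_event = age, prob = prob, stringsAsFactors = FALSE)
}

#' Expected terminal-state counts (analytic rollback)
#'
#' @param root `ec_node`.
#' @param n_patients Cohort size (>= 0).
#' @return Terminal-state table with an `expected` column summing to
#'   `n_patients`.
#' @export
evaluate_tree <- function(root, n_patients) {
  if (n_patients < 0) stop("n_patients must be >= 0", call. = FALSE)
  paths <- tree_paths(root)
  paths$expected <- n_patients * paths$prob
  paths
}

#' Sampled terminal-state counts (micro-simulation)
#'
#' Traverses the tree once per patient by sampling each patient's
#' root-to-leaf path (implemented as one categorical draw per patient over
#' the enumerated paths, which is distributionally identical).  Counts
#' converge on the [evaluate_tree()] expectations.
#'
#' @param root `ec_node`.
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed.
#' @return Terminal-state table with a sampled `count` column summing to
#'   `n_patients`.
#' @export
microsimulate <- function(root, n_patients, seed = 1) {
  paths <- tree_paths(root)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  paths$count <- as.numeric(
    stats::rmultinom(1, size = n_patients, prob = paths$prob))
  paths
}

#' Serialise a tree to JSON
#'
#' @param root `ec_node`.
#' @param path Optional file to write to.
#' @return JSON string (invisibly if written to file).
#' @export
tree_to_json <- function(root, path = NULL) {
  strip <- function(node) {
    if (inherits(node, "ec_terminal")) {
      list(label = node$label, state = node$state,
           condition = node$condition, age_at_event = node$age_at_event,
           rehab_flag = node$rehab_flag)
    } else {
      list(label = node$label,
           branches = lapply(node$branches, function(b) {
             list(p = b$p, node = strip(b$node))
           }))
    }
  }
  js <- jsonlite::toJSON(strip(root), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Export a tree as Graphviz DOT
#'
#' @param root `ec_node`.
#' @param path Optional file to write to.
#' @return Character scalar of DOT source.
#' @export
tree_to_dot <- function(root, path = NULL) {
  lines <- c("digraph decision_tree {", "  node [shape=box];")
  counter <- 0L
  emit <- function(node) {
    counter <<- counter + 1L
    id <- paste0("n", counter)
    label <- gsub('"', "'", node$label)
    shape <- if (inherits(node, "ec_terminal")) "oval" else "box"
    lines <<- c(lines, sprintf('  %s [label="%s", shape=%s];', id, label,
                               shape))
    if (!inherits(node, "ec_terminal")) {
      for (b in node$branches) {
        cid <- emit(b$node)
        lines <<- c(lines, sprintf('  %s -> %s [label="%.4g"];', id, cid,
                                   b$p))
      }
    }
    id
  }
  emit(root)
  out <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) writeLines(out, path)
  out
}
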