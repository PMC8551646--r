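#' Configuration of the differential-effect search
#'
#' @param M Covariate width: at each node only the best `M` covariates
#'   (by multiplicity-adjusted split p) spawn children. Default 5.
#' @param L Maximum rule depth (number of intersected conditions).
#'   Default 3.
#' @param gamma Per-level continuation multipliers in (0, 1], recycled to
#'   length `L`. A child created at depth l is promising only if its
#'   adjusted split p is at most `gamma[l] * parent_p`. Default 1: each
#'   child must be at least as significant as its parent.
#' @param min_node Minimum records per contrast group in each child node.
#'   Default 30.
#' @param min_events For binary outcomes, minimum events per arm in each
#'   child. Default 5.
#' @param alpha Significance level used when reporting adjusted p-values.
#'   Default 0.05.
#' @param B Number of permutation resamples for adjusted p-values.
#'   Default 1000.
#' @param seed Integer seed for the permutation stream. Default 1.
#' @param adjust Per-covariate multiplicity adjustment: a function of the
#'   best split p-value and the admissible candidate count. Defaults to
#'   the Šidák form [multiplicity_adjust()]; swap in another form (e.g.
#'   Bonferroni `function(p, n) pmin(1, p * n)`) to change how
#'   many-levelled covariates are penalised.
#' @return A `sides_config` list.
#' @export
sides_config <- function(M = 5, L = 3, gamma = 1, min_node = 30,
                         min_events = 5, alpha = 0.05, B = 1000, seed = 1,
                         adjust = multiplicity_adjust) {
  if (M < 1) abort("M must be >= 1.")
  if (L < 1) abort("L must be >= 1.")
  gamma <- rep_len(as.numeric(gamma), L)
  if (any(gamma <= 0 | gamma > 1)) abort("gamma multipliers must lie in (0, 1].")
  if (min_node < 1) abort("min_node must be >= 1.")
  if (!is.function(adjust)) abort("adjust must be a function(p, n_candidates).")
  structure(
    list(M = as.integer(M), L = as.integer(L), gamma = gamma,
         min_node = min_node, min_events = min_events,
         alpha = alpha, B = as.integer(B), seed = as.integer(seed),
         adjust = adjust),
    class = "sides_config"
  )
}

#' Continuation (complexity) criterion
#'
#' A child node continues the recursion only if it improves sufficiently
#' on its parent: `child_p <= gamma_l * parent_p`. The root's parent p is
#' taken as 1, so first-level children are judged purely on their own
#' criterion.
#'
#' @param child_p Child's multiplicity-adjusted split p-value, in (0, 1].
#' @param parent_p Parent's value (1 for the root).
#' @param gamma_l Continuation multiplier at this level.
#' @return `TRUE` if the child qualifies as promising.
#' @export
continuation_check <- function(child_p, parent_p, gamma_l = 1) {
  if (any(child_p <= 0 | child_p > 1) || any(parent_p <= 0 | parent_p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  child_p <= gamma_l * parent_p
}

#' Run the recursive differential-effect search
#'
#' The search ranks covariates at each node ([rank_covariates()]), carries
#' the promising (larger-z) child of each of the best `M` splits forward
#' when it passes the continuation criterion, and recurses to depth `L`.
#' All subgroup statistics are centered at the whole-sample gap `D`
#' ([overall_offset()]), computed once and held fixed, so each node tests
#' for an excess gap over the full sample. Reported subgroups may
#' overlap; identical rules reached along different paths are reported
#' once (with the smallest creating p). The run is deterministic given
#' its inputs. Permutation-adjusted p-values are added by [sides()].
#'
#' @param table A `survey_table`.
#' @param outcome Outcome name or [outcome_spec()].
#' @param covariates Optional character vector of covariates to search.
#' @param config A [sides_config()].
#' @return A tibble of promising subgroups (class `sides_subgroups`):
#'   `rule`, `depth`, `p_split` (adjusted split p that created the node),
#'   `z` (centered statistic), per-group counts and summaries, `diff`,
#'   `se`, `ci_low`, `ci_high`, and the `subgroup_rule` objects in the
#'   `rule_obj` list-column. The offset `D`, outcome and config are
#'   attached as attributes.
#' @export
run_sides <- function(table, outcome, covariates = NULL,
                      config = sides_config()) {
  stopifnot(inherits(config, "sides_config"))
  prep <- engine_prep(table, outcome, covariates)
  D <- engine_offset(prep)
  nodes <- sides_engine(prep, config, D)
  out <- format_nodes(nodes, prep, config)
  attr(out, "offset") <- structure(list(D = D, outcome = prep$spec$name),
                                   class = "centering_offset")
  attr(out, "outcome") <- prep$spec
  attr(out, "config") <- config
  out
}

format_nodes <- function(nodes, prep, config, ci_mult = 1.96) {
  if (!length(nodes)) {
    out <- tibble::tibble(
      rule = character(), depth = integer(), p_split = numeric(),
      z = numeric(), n1 = numeric(), n2 = numeric(),
      summary1 = numeric(), summary2 = numeric(), diff = numeric(),
      se = numeric(), ci_low = numeric(), ci_high = numeric(),
      rule_obj = list()
    )
  } else {
    out <- purrr::map_dfr(nodes, function(nd) {
      diff <- prep$sign * (nd$m2 - nd$m1)
      tibble::tibble(
        rule = format(nd$rule), depth = nd$depth, p_split = nd$p,
        z = nd$z, n1 = nd$n1, n2 = nd$n2,
        summary1 = nd$m1, summary2 = nd$m2, diff = diff, se = nd$se,
        ci_low = diff - ci_mult * nd$se, ci_high = diff + ci_mult * nd$se,
        rule_obj = list(nd$rule)
      )
    })
    out <- out[order(out$p_split, out$depth, out$rule), ]
  }
  class(out) <- c("sides_subgroups", class(tibble::tibble()))
  out
}
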