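#' Does a rule contain a given condition?
#'
#' Conditions match on covariate, operator and value set (order-free for
#' `in` subsets). Useful for checking recovery of a planted rule.
#'
#' @param rule A [subgroup_rule()].
#' @param cond A [condition()], or a `subgroup_rule` whose conditions must
#'   all be contained.
#' @return Logical.
#' @export
rule_contains <- function(rule, cond) {
  stopifnot(inherits(rule, "subgroup_rule"))
  if (inherits(cond, "subgroup_rule")) {
    return(all(vapply(cond$conditions, rule_contains, logical(1),
                      rule = rule)))
  }
  any(vapply(rule$conditions, function(c2) {
    c2$covariate == cond$covariate && c2$op == cond$op &&
      setequal(c2$value, cond$value)
  }, logical(1)))
}

#' Type-I-error study under a homogeneous-gap generator
#'
#' Simulates `replicates` null datasets (no planted interactions), runs
#' the full search with permutation adjustment on each, and records
#' whether any subgroup reaches `alpha`. With a valid permutation null
#' the family-wise rate of such false discoveries should not
#' systematically exceed `alpha`.
#'
#' @param config A [generator_config()]; its planted interactions are
#'   removed via [null_config()] if present.
#' @param outcome Outcome name.
#' @param replicates Number of simulated datasets.
#' @param sconfig A [sides_config()] (its `B` drives the permutations).
#' @param seed Base seed; replicate r generates with `seed + r` and
#'   permutes with `seed + 100000 + r`.
#' @param alpha Significance threshold.
#' @return A tibble with one row per replicate: `replicate`,
#'   `n_subgroups`, `min_adjusted_p`, `significant`; the false-positive
#'   proportion is attached as attribute `rate`.
#' @export
null_calibration <- function(config, outcome, replicates = 200,
                             sconfig = sides_config(B = 99), seed = 1,
                             alpha = sconfig$alpha) {
  config <- null_config(config)
  old_level <- set_log_level("quiet")     # one log line per fit is noise here
  on.exit(set_log_level(old_level))
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    tab <- generate_survey(config, seed = seed + r)
    fit <- sides(tab, outcome, config = sconfig, B = sconfig$B,
                 seed = seed + 100000L + r)
    minp <- if (nrow(fit$subgroups)) min(fit$subgroups$adjusted_p) else NA_real_
    tibble::tibble(replicate = r, n_subgroups = nrow(fit$subgroups),
                   min_adjusted_p = minp,
                   significant = !is.na(minp) && minp < alpha)
  })
  attr(rows, "rate") <- mean(rows$significant)
  rows
}

#' Recovery study for a planted subgroup rule
#'
#' Simulates `replicates` datasets from a configuration with planted
#' interactions and records, for each, whether the search (before
#' permutation adjustment) reports a promising subgroup whose rule
#' contains every planted condition.
#'
#' @param config A [generator_config()] with a planted rule.
#' @param outcome Outcome name(s). With several outcomes (the planted
#'   social location typically carries an excess gap on every outcome of
#'   the study), a dataset counts as recovered when the rule is reported
#'   for at least one of them.
#' @param rule The planted [subgroup_rule()]; defaults to the rule of the
#'   first outcome's model.
#' @param replicates Number of simulated datasets.
#' @param sconfig A [sides_config()].
#' @param seed Base seed (replicate r uses `seed + r`).
#' @return A tibble with `replicate`, one logical column per outcome, and
#'   `recovered`; the recovery proportion is attached as attribute
#'   `rate`.
#' @export
planted_recovery <- function(config, outcome, rule = NULL, replicates = 50,
                             sconfig = sides_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  rule <- rule %||% config$models[[outcome[1]]]$rule
  if (is.null(rule)) abort("no planted rule for this outcome.")
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    tab <- generate_survey(config, seed = seed + r)
    hits <- vapply(outcome, function(oc) {
      sub <- run_sides(tab, oc, config = sconfig)
      any(vapply(sub$rule_obj, rule_contains, logical(1), cond = rule))
    }, logical(1))
    out <- tibble::tibble(replicate = r)
    out[outcome] <- as.list(hits)
    out$recovered <- any(hits)
    out
  })
  attr(rows, "rate") <- mean(rows$recovered)
  rows
}
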