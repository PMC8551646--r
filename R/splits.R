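#' Enumerate candidate bipartitions of a covariate
#'
#' Ordinal covariates with k observed levels yield the k-1 threshold
#' partitions respecting the level order; nominal covariates yield the
#' 2^(k-1)-1 distinct bipartitions by level subset (each unordered pair of
#' complementary subsets once). Only levels observed among the node's
#' records count. Nominal covariates with more than 12 observed levels
#' are rejected rather than enumerated.
#'
#' @param table A `survey_table` (the node).
#' @param covariate Covariate name or [covariate_schema()].
#' @return A list of partitions; each is a list with `child1` and `child2`
#'   [condition()]s. Empty when fewer than two levels are observed.
#' @export
enumerate_splits <- function(table, covariate) {
  schema <- table_schema(table)
  cv <- if (inherits(covariate, "covariate_schema")) covariate else {
    resolve_covariates(schema, covariate)[[1]]
  }
  x <- table[[cv$name]]
  obs <- which(tabulate(as.integer(x), length(cv$levels)) > 0L)
  ko <- length(obs)
  if (ko < 2L) return(list())
  if (cv$kind == "ordinal") {
    lapply(seq_len(ko - 1L), function(t) {
      list(child1 = condition(cv$name, "le", cv$levels[obs[t]]),
           child2 = condition(cv$name, "ge", cv$levels[obs[t] + 1L]))
    })
  } else {
    if (ko > 12L) {
      abort(sprintf("nominal covariate '%s' has %d observed levels; refusing to enumerate %s bipartitions.",
                    cv$name, ko, format(2^(ko - 1) - 1, big.mark = ",")))
    }
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), ko - 1L)))[-1L, , drop = FALSE]
    lapply(seq_len(nrow(masks)), function(i) {
      side <- obs[c(masks[i, ], FALSE)]
      list(child1 = condition(cv$name, "in", cv$levels[side]),
           child2 = condition(cv$name, "in", cv$levels[setdiff(obs, side)]))
    })
  }
}

#' Sidak multiplicity adjustment over a covariate's candidate splits
#'
#' Adjusts the best split p-value for the number of candidate partitions
#' the covariate offered, `1 - (1 - p)^n`, removing the advantage of
#' covariates with many potential splits. Non-decreasing in `n_candidates`
#' and the identity at `n_candidates = 1`.
#'
#' @param p_min Best (minimum) split p-value, in (0, 1].
#' @param n_candidates Number of admissible candidate partitions (>= 1).
#' @return The adjusted p-value, capped at 1.
#' @export
multiplicity_adjust <- function(p_min, n_candidates) {
  if (any(p_min <= 0 | p_min > 1)) abort("p_min must lie in (0, 1].")
  if (any(n_candidates < 1)) abort("n_candidates must be >= 1.")
  sidak_adjust(p_min, n_candidates)
}

#' Best admissible split of one covariate at a node
#'
#' Scores every admissible bipartition from [enumerate_splits()] with the
#' two-child criterion of [split_pvalue()] on centered statistics and
#' returns the minimiser. Partitions are admissible when each child holds
#' at least `min_node` records per contrast group (and, for binary
#' outcomes, `min_events` events per arm, guarding the normal
#' approximation).
#'
#' @param table A `survey_table` (the node).
#' @param covariate Covariate name.
#' @param outcome Outcome name or [outcome_spec()].
#' @param offset A `centering_offset` from [overall_offset()] (or number).
#' @param min_node Minimum records per contrast group per child.
#' @param min_events Minimum events per arm per child (binary outcomes).
#' @return A `split_candidate` (list with the promising-child condition,
#'   `z1`, `z2`, `p_split`, multiplicity-adjusted `p_adj`, candidate count
#'   and child-by-group counts), or `NULL` when no admissible split
#'   exists.
#' @export
best_split <- function(table, covariate, outcome, offset,
                       min_node = 30, min_events = 5) {
  schema <- table_schema(table)
  covs <- resolve_covariates(schema, covariate)
  prep <- engine_prep(table, outcome, NULL)
  j <- match(names(covs)[1], names(prep$covs))
  D <- if (inherits(offset, "centering_offset")) offset$D else as.numeric(offset)
  sc <- score_covariate(prep, seq_len(prep$n), j, D, min_node, min_events)
  if (is.null(sc)) return(NULL)
  as_split_candidate(sc)
}

as_split_candidate <- function(sc) {
  structure(
    list(covariate = sc$covariate, condition = sc$cond,
         z1 = sc$z1, z2 = sc$z2, z_promising = sc$z,
         p_split = sc$p, n_candidates = sc$ncand, p_adj = sc$p_adj,
         n_per_arm = sc$n_per_arm,
         child_n1 = sc$n1, child_n2 = sc$n2,
         child_summary1 = sc$m1, child_summary2 = sc$m2,
         child_se = sc$se),
    class = "split_candidate"
  )
}

#' @export
print.split_candidate <- function(x, ...) {
  cat(sprintf("<split_candidate> %s | promising child: %s\n  z1 = %.3f, z2 = %.3f, p_split = %.4g (adj %.4g over %d candidates)\n",
              x$covariate, format_condition(x$condition), x$z1, x$z2,
              x$p_split, x$p_adj, x$n_candidates))
  invisible(x)
}

#' Rank covariates by adjusted best-split p-value
#'
#' Each usable covariate contributes its best admissible split,
#' multiplicity-adjusted with [multiplicity_adjust()]; covariates are
#' ranked ascending by adjusted p (ties broken by schema declaration
#' order) and truncated to the best `M`.
#'
#' @inheritParams best_split
#' @param covariates Character vector of covariate names (default: all).
#' @param M Number of covariates retained.
#' @param adjust Multiplicity-adjustment function of `(p, n_candidates)`;
#'   defaults to [multiplicity_adjust()].
#' @return A tibble with one row per retained covariate: `covariate`,
#'   `p_split`, `n_candidates`, `p_adj`, `z1`, `z2`, and the promising
#'   child's condition as text; the underlying `split_candidate` objects
#'   sit in the `candidate` list-column.
#' @export
rank_covariates <- function(table, covariates = NULL, outcome, offset, M = 5,
                            min_node = 30, min_events = 5,
                            adjust = multiplicity_adjust) {
  if (M < 1) abort("M must be >= 1.")
  prep <- engine_prep(table, outcome, covariates)
  D <- if (inherits(offset, "centering_offset")) offset$D else as.numeric(offset)
  cfg <- list(M = M, min_node = min_node, min_events = min_events,
              adjust = adjust)
  ranked <- rank_node(prep, seq_len(prep$n), seq_along(prep$covs), D, cfg)
  purrr::map_dfr(ranked, function(sc) {
    tibble::tibble(
      covariate = sc$covariate,
      condition = format_condition(sc$cond),
      p_split = sc$p, n_candidates = sc$ncand, p_adj = sc$p_adj,
      z1 = sc$z1, z2 = sc$z2,
      candidate = list(as_split_candidate(sc))
    )
  })
}
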