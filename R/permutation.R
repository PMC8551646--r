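#' Permutation null distribution of the search's minimal criterion p
#'
#' For each of `B` resamples the contrast labels are permuted uniformly at
#' random over all records, the centering offset `D` is recomputed on the
#' permuted data (so the null of "no excess over the overall gap" is
#' preserved), the full search is re-run with the identical configuration,
#' and the minimal multiplicity-adjusted split p across its discovered
#' subgroups (1 if none) is recorded. Reproducible given `seed`.
#'
#' @inheritParams run_sides
#' @param B Number of permutation resamples.
#' @param seed Integer seed.
#' @return A `null_distribution`: list with `B`, `min_p` (length `B`) and
#'   `seed`.
#' @export
permutation_null <- function(table, outcome, covariates = NULL,
                             config = sides_config(), B = config$B,
                             seed = config$seed) {
  if (B < 1) abort("B must be >= 1.")
  prep <- engine_prep(table, outcome, covariates)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  min_p <- vapply(seq_len(B), function(b) {
    gp <- prep$g[sample.int(prep$n)]
    Dp <- engine_offset(prep, gp)
    nodes <- sides_engine(prep, config, Dp, g = gp)
    if (!length(nodes)) 1 else min(vapply(nodes, `[[`, numeric(1), "p"))
  }, numeric(1))
  structure(list(B = as.integer(B), min_p = min_p, seed = as.integer(seed)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> B = %d permutations (seed %d); min_p quartiles %s\n",
              x$B, x$seed,
              paste(signif(stats::quantile(x$min_p, c(.25, .5, .75)), 3),
                    collapse = " / ")))
  invisible(x)
}

#' Permutation-adjusted p-value
#'
#' Add-one permutation p-value of an observed criterion p against the
#' null distribution of minimal criterion p-values:
#' `(1 + #\{b: min_p_b <= observed\}) / (B + 1)`. Non-decreasing in the
#' observed p and bounded in `[1/(B+1), 1]`.
#'
#' @param observed_p Observed criterion p-value(s), in (0, 1].
#' @param null A `null_distribution` from [permutation_null()].
#' @return Adjusted p-value(s).
#' @export
adjusted_pvalue <- function(observed_p, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (any(observed_p <= 0 | observed_p > 1)) abort("observed_p must lie in (0, 1].")
  vapply(observed_p,
         function(p) (1 + sum(null$min_p <= p)) / (null$B + 1),
         numeric(1))
}

#' Differential-effect subgroup search with permutation adjustment
#'
#' The package's main entry point: runs [run_sides()], builds the
#' permutation null with [permutation_null()], and attaches a
#' resampling-adjusted p-value to every promising subgroup.
#'
#' @inheritParams run_sides
#' @param B Number of permutation resamples (defaults to `config$B`).
#' @param seed Seed for the permutation stream (defaults to
#'   `config$seed`).
#' @return A `sides_fit` object; see [tidy.sides_fit()],
#'   [glance.sides_fit()], [autoplot.sides_fit()].
#' @examples
#' \donttest{
#' cfg <- default_survey_config(n_per_group = c(4000, 4000))
#' tab <- generate_survey(cfg, seed = 7)
#' fit <- sides(tab, "diagnosis", config = sides_config(B = 99, seed = 7))
#' tidy(fit)
#' }
#' @export
sides <- function(table, outcome, covariates = NULL, config = sides_config(),
                  B = config$B, seed = config$seed) {
  subgroups <- run_sides(table, outcome, covariates, config)
  null <- permutation_null(table, outcome, covariates, config, B = B,
                           seed = seed)
  subgroups$adjusted_p <- if (nrow(subgroups)) {
    adjusted_pvalue(subgroups$p_split, null)
  } else {
    numeric()
  }
  offset <- attr(subgroups, "offset")
  log_info("centering offset D = %.6g for outcome '%s'", offset$D,
           offset$outcome)
  structure(
    list(
      subgroups = subgroups,
      overall = group_effect(table, outcome),
      offset = offset,
      null = null,
      outcome = attr(subgroups, "outcome"),
      config = config,
      schema = table_schema(table),
      n = nrow(table)
    ),
    class = "sides_fit"
  )
}

#' @export
print.sides_fit <- function(x, ...) {
  cat(sprintf("<sides_fit> outcome '%s' (%s), n = %d\n", x$outcome$name,
              x$outcome$measure, x$n))
  cat(sprintf("  overall gap D = %.4g (95%% CI %.4g, %.4g)\n",
              x$overall$diff, x$overall$ci_low, x$overall$ci_high))
  cat(sprintf("  %d promising subgroup(s); %d with adjusted p < %.3g (B = %d)\n",
              nrow(x$subgroups),
              sum(x$subgroups$adjusted_p < x$config$alpha),
              x$config$alpha, x$null$B))
  if (nrow(x$subgroups)) {
    top <- utils::head(x$subgroups, 5)
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s: gap %.4g (%.4g, %.4g), adj p = %.4g\n",
                  top$rule[i], top$diff[i], top$ci_low[i], top$ci_high[i],
                  top$adjusted_p[i]))
    }
  }
  invisible(x)
}

#' Tidy the discovered subgroups of a fit
#'
#' @param x A `sides_fit`.
#' @param ... Unused.
#' @return The subgroup tibble of [run_sides()] plus `adjusted_p`.
#' @export
tidy.sides_fit <- function(x, ...) {
  out <- x$subgroups
  attr(out, "offset") <- NULL
  attr(out, "outcome") <- NULL
  attr(out, "config") <- NULL
  tibble::as_tibble(out)
}

#' One-row summary of a fit
#'
#' @param x A `sides_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `outcome`, `n`, overall `D` with CI,
#'   `n_subgroups`, `n_significant` (adjusted p below `alpha`),
#'   `min_adjusted_p`, `B`.
#' @export
glance.sides_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome$name,
    n = x$n,
    D = x$offset$D,
    ci_low = x$overall$ci_low,
    ci_high = x$overall$ci_high,
    n_subgroups = nrow(x$subgroups),
    n_significant = sum(x$subgroups$adjusted_p < x$config$alpha),
    min_adjusted_p = if (nrow(x$subgroups)) min(x$subgroups$adjusted_p) else NA_real_,
    B = x$null$B
  )
}

#' Forest plot of subgroup gaps
#'
#' Subgroup gap estimates with 95% intervals against the overall gap
#' (dashed line), ordered by adjusted p-value.
#'
#' @param object A `sides_fit`.
#' @param max_subgroups Show at most this many subgroups (smallest
#'   adjusted p first). Default 15.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sides_fit <- function(object, max_subgroups = 15, ...) {
  sub <- utils::head(dplyr::arrange(tidy(object), .data$adjusted_p,
                                    .data$p_split), max_subgroups)
  lab <- sprintf("overall (%s)", object$outcome$name)
  dat <- dplyr::bind_rows(
    tibble::tibble(rule = lab, diff = object$overall$diff,
                   ci_low = object$overall$ci_low,
                   ci_high = object$overall$ci_high,
                   adjusted_p = NA_real_),
    dplyr::select(sub, "rule", "diff", "ci_low", "ci_high", "adjusted_p")
  )
  dat$rule <- factor(dat$rule, levels = rev(dat$rule))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$diff, y = .data$rule)) +
    ggplot2::geom_vline(xintercept = object$offset$D, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::labs(
      x = sprintf("%s gap (%s)", object$outcome$name,
                  if (object$outcome$measure == "binary") "difference in proportions"
                  else "difference in means"),
      y = NULL,
      title = "Subgroups with amplified group differences",
      subtitle = sprintf("dashed line: overall gap D = %.3g", object$offset$D)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
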