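#' Two-group effect estimate for one outcome
#'
#' Continuous outcomes: difference of group means with unpooled
#' (Welch-type) standard error `sqrt(s1^2/n1 + s2^2/n2)`. Binary
#' outcomes: difference of proportions with
#' `sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`. The difference is oriented as
#' `disadvantage_sign * (group2 - group1)` so the gap of interest is
#' positive, and the 95% CI is `diff +/- ci_mult * se`.
#'
#' @param table A `survey_table` (often a subgroup from [apply_rule()]).
#' @param outcome Outcome name or [outcome_spec()].
#' @param ci_mult CI half-width multiplier (default 1.96).
#' @param se_type `"unpooled"` (default; Welch-type for means, standard
#'   binomial for proportions) or `"pooled"` (common-variance /
#'   common-proportion forms).
#' @return An `effect_estimate`: list with `diff`, `se`, `ci_low`,
#'   `ci_high`, `n1`, `n2`, `summary1`, `summary2` (group means or
#'   proportions), `outcome`, `measure`.
#' @examples
#' # 30/1000 vs 90/1000 events: diff 0.06
#' df <- data.frame(g = rep(c("a", "b"), each = 1000),
#'                  y = c(rep(1, 30), rep(0, 970), rep(1, 90), rep(0, 910)),
#'                  x = "u")
#' sch <- survey_schema("g", c("a", "b"),
#'                      list(covariate_schema("x", "nominal", c("u", "v"))),
#'                      list(outcome_spec("y", "binary")))
#' group_effect(survey_table(df, sch), "y")$diff
#' @export
group_effect <- function(table, outcome, ci_mult = 1.96,
                         se_type = c("unpooled", "pooled")) {
  se_type <- match.arg(se_type)
  schema <- table_schema(table)
  spec <- resolve_outcome(schema, outcome)
  y <- table[[spec$name]]
  g <- as.integer(table[[schema$contrast]])
  ok <- !is.na(y) & !is.na(g)
  y1 <- y[ok & g == 1L]
  y2 <- y[ok & g == 2L]
  n1 <- length(y1)
  n2 <- length(y2)
  if (n1 < 2L || n2 < 2L) {
    abort(sprintf("outcome '%s': need >= 2 non-missing values per contrast group (got %d, %d).",
                  spec$name, n1, n2))
  }
  m1 <- mean(y1)
  m2 <- mean(y2)
  se <- if (spec$measure == "binary") {
    if (se_type == "pooled") {
      pbar <- (sum(y1) + sum(y2)) / (n1 + n2)
      sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    } else {
      sqrt(m1 * (1 - m1) / n1 + m2 * (1 - m2) / n2)
    }
  } else if (se_type == "pooled") {
    sp2 <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    sqrt(var(y1) / n1 + var(y2) / n2)
  }
  if (se == 0) {
    abort(sprintf("outcome '%s': zero variance in both groups (degenerate node).",
                  spec$name))
  }
  diff <- spec$disadvantage_sign * (m2 - m1)
  structure(
    list(diff = diff, se = se,
         ci_low = diff - ci_mult * se, ci_high = diff + ci_mult * se,
         n1 = n1, n2 = n2, summary1 = m1, summary2 = m2,
         outcome = spec$name, measure = spec$measure,
         sign = spec$disadvantage_sign),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: diff %.4g (95%% CI %.4g, %.4g), se %.4g, n = %d / %d\n",
              x$outcome, x$diff, x$ci_low, x$ci_high, x$se, x$n1, x$n2))
  invisible(x)
}

#' @rdname group_effect
#' @param x An `effect_estimate`.
#' @param ... Unused.
#' @export
tidy.effect_estimate <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, diff = x$diff, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high,
    summary1 = x$summary1, summary2 = x$summary2,
    n1 = x$n1, n2 = x$n2
  )
}

#' Whole-sample centering offset D
#'
#' The differential-effect search tests each subgroup for an *excess*
#' gap over the whole sample: subgroup statistics are centered at D, the
#' full-sample group difference on the disadvantage-sign convention.
#'
#' @param table The full `survey_table`.
#' @param outcome Outcome name or [outcome_spec()].
#' @return A `centering_offset` with field `D`.
#' @export
overall_offset <- function(table, outcome) {
  eff <- group_effect(table, outcome)
  structure(list(D = eff$diff, outcome = eff$outcome),
            class = "centering_offset")
}

#' Centered subgroup statistic
#'
#' `Z_S = (diff_S - D) / se_S`: the subgroup's group difference minus the
#' whole-sample difference, scaled by the subgroup estimator's standard
#' error. The full sample against its own offset gives exactly 0.
#'
#' @param effect An `effect_estimate` for the subgroup.
#' @param offset A `centering_offset` (or a single number D).
#' @return The centered z statistic.
#' @export
centered_z <- function(effect, offset) {
  D <- if (inherits(offset, "centering_offset")) offset$D else as.numeric(offset)
  if (!is.finite(D)) abort("centering offset D must be finite.")
  if (!inherits(effect, "effect_estimate")) abort("`effect` must be an effect_estimate.")
  if (effect$se <= 0) abort("degenerate node: se must be > 0 for a centered z.")
  (effect$diff - D) / effect$se
}

#' Two-child splitting criterion p-value
#'
#' `p_split = 2 * min(1 - Phi(z1), 1 - Phi(z2))`, capped at 1, where Phi
#' is the standard normal CDF: twice the smaller upper-tail p-value of the
#' two child statistics. Symmetric in its arguments and non-increasing in
#' each. Vectorised.
#'
#' @param z1,z2 Centered statistics of the two children of a candidate
#'   split.
#' @return p-value(s) in (0, 1].
#' @export
split_pvalue <- function(z1, z2) {
  if (anyNA(z1) || anyNA(z2)) abort("z1 and z2 must be non-missing.")
  p <- 2 * pnorm(pmax(z1, z2), lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}
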