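#' A single subgroup condition
#'
#' Conditions come in three forms: `le`/`ge` thresholds on ordinal
#' covariates (`grade <= "8"`, `grade >= "9"`) and `in` subsets on nominal
#' ones (`family_structure in {Mother only, Father only}`). Thresholds
#' must lie strictly inside the level order (a condition satisfied by
#' every level is not a condition), and `in` subsets must be non-empty
#' proper subsets of the declared levels.
#'
#' @param covariate Covariate name.
#' @param op One of `"le"`, `"ge"`, `"in"`.
#' @param value For `le`/`ge`, a single level label; for `in`, a character
#'   vector of level labels.
#' @return A `condition` object.
#' @examples
#' condition("grade", "ge", "9")
#' condition("affluence", "in", "Low")
#' @export
condition <- function(covariate, op = c("le", "ge", "in"), value) {
  op <- match.arg(op)
  value <- as.character(value)
  if (op != "in" && length(value) != 1L) {
    abort("le/ge conditions take a single threshold level.")
  }
  if (op == "in" && length(value) < 1L) abort("`in` conditions need >= 1 level.")
  structure(list(covariate = covariate, op = op, value = value),
            class = "condition")
}

#' A conjunction of conditions defining a subgroup
#'
#' @param ... `condition` objects (possibly none: the empty rule selects
#'   everyone). At most one condition per covariate.
#' @return A `subgroup_rule` object; its depth is the number of conditions.
#' @examples
#' subgroup_rule(condition("grade", "ge", "9"),
#'               condition("affluence", "in", "Low"))
#' @export
subgroup_rule <- function(...) {
  conds <- list(...)
  if (length(conds) == 1L && is.list(conds[[1]]) &&
      !inherits(conds[[1]], "condition")) {
    conds <- conds[[1]]
  }
  if (!all(vapply(conds, inherits, logical(1), "condition"))) {
    abort("all rule components must be condition objects.")
  }
  covs <- vapply(conds, `[[`, character(1), "covariate")
  if (anyDuplicated(covs)) {
    abort("a rule may carry at most one condition per covariate.")
  }
  structure(list(conditions = conds), class = "subgroup_rule")
}

#' @export
length.subgroup_rule <- function(x) length(x$conditions)

rule_depth <- function(rule) length(rule$conditions)

#' Render a rule in canonical text form
#'
#' @param x A `subgroup_rule`.
#' @param ... Unused.
#' @return A string such as `"grade>=9 & affluence in {Low}"`; the empty
#'   rule renders as `"<all records>"`.
#' @export
format.subgroup_rule <- function(x, ...) {
  if (!length(x$conditions)) return("<all records>")
  paste(vapply(x$conditions, format_condition, character(1)), collapse = " & ")
}

format_condition <- function(cond) {
  switch(cond$op,
    le = sprintf("%s<=%s", cond$covariate, cond$value),
    ge = sprintf("%s>=%s", cond$covariate, cond$value),
    `in` = sprintf("%s in {%s}", cond$covariate,
                   paste(cond$value, collapse = ", ")))
}

#' @export
print.subgroup_rule <- function(x, ...) {
  cat("<subgroup_rule> ", format(x), "\n", sep = "")
  invisible(x)
}

validate_condition <- function(cond, schema) {
  cv <- schema$covariates[[cond$covariate]]
  if (is.null(cv)) abort(sprintf("unknown covariate in rule: '%s'", cond$covariate))
  bad <- setdiff(cond$value, cv$levels)
  if (length(bad)) {
    abort(sprintf("condition on '%s' names undeclared level(s): %s",
                  cond$covariate, paste(bad, collapse = ", ")))
  }
  k <- length(cv$levels)
  if (cond$op %in% c("le", "ge")) {
    if (cv$kind != "ordinal") {
      abort(sprintf("le/ge conditions require an ordinal covariate ('%s' is %s).",
                    cond$covariate, cv$kind))
    }
    i <- match(cond$value, cv$levels)
    if ((cond$op == "le" && i >= k) || (cond$op == "ge" && i <= 1L)) {
      abort(sprintf("threshold on '%s' must lie strictly inside the level order.",
                    cond$covariate))
    }
  } else if (length(cond$value) >= k) {
    abort(sprintf("`in` subset on '%s' must be a proper subset of its levels.",
                  cond$covariate))
  }
  invisible(cond)
}

condition_mask <- function(cond, table, schema) {
  validate_condition(cond, schema)
  cv <- schema$covariates[[cond$covariate]]
  code <- as.integer(table[[cond$covariate]])
  thr <- match(cond$value[1], cv$levels)
  m <- switch(cond$op,
    le = code <= thr,
    ge = code >= thr,
    `in` = code %in% match(cond$value, cv$levels))
  m & !is.na(code)
}

#' Select the records satisfying a rule
#'
#' Records missing a value on any of the rule's covariates satisfy none of
#' its conditions and are excluded (complete-case per split).
#'
#' @param table A `survey_table`.
#' @param rule A [subgroup_rule()]; the empty rule returns the table
#'   unchanged.
#' @return The matching `survey_table` subset.
#' @export
apply_rule <- function(table, rule) {
  schema <- table_schema(table)
  keep <- rule_mask(table, rule, schema)
  new_survey_table(tibble::as_tibble(table)[keep, , drop = FALSE], schema)
}

rule_mask <- function(table, rule, schema = table_schema(table)) {
  stopifnot(inherits(rule, "subgroup_rule"))
  keep <- rep(TRUE, nrow(table))
  for (cond in rule$conditions) {
    keep <- keep & condition_mask(cond, table, schema)
  }
  keep
}

# Canonical de-duplication key: conditions sorted by covariate; nominal
# subsets are represented by the lexicographically smaller of the subset
# and its complement within the declared levels, so the same bipartition
# reached along different search paths collapses to one key.
rule_key <- function(rule, schema) {
  if (!length(rule$conditions)) return("<root>")
  parts <- vapply(rule$conditions, function(cond) {
    cv <- schema$covariates[[cond$covariate]]
    if (cond$op == "in") {
      side <- paste(sort(cond$value), collapse = "|")
      comp <- paste(sort(setdiff(cv$levels, cond$value)), collapse = "|")
      pick <- if (length(cond$value) < length(cv$levels) - length(cond$value) ||
                  (length(cond$value) == length(cv$levels) - length(cond$value) &&
                   side <= comp)) {
        sprintf("{%s}", side)
      } else {
        sprintf("!{%s}", comp)
      }
      sprintf("%s:%s", cond$covariate, pick)
    } else {
      sprintf("%s:%s%s", cond$covariate, cond$op, match(cond$value, cv$levels))
    }
  }, character(1))
  paste(sort(parts), collapse = " & ")
}
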