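#' Declare a categorical survey covariate
#'
#' A covariate ("social location" variable) is either ordinal, in which
#' case the order of `levels` is meaningful and binary splits respect it,
#' or nominal, in which case splits range over level subsets.
#'
#' @param name Column name in the survey table.
#' @param kind `"ordinal"` or `"nominal"`.
#' @param levels Character vector of admissible level labels, ordered for
#'   ordinal covariates. Must be unique and non-empty.
#' @param missing_label Optional label (e.g. `"Missing"`) treated as a
#'   missing value on input, in addition to empty cells.
#' @return An object of class `covariate_schema`.
#' @examples
#' covariate_schema("grade", "ordinal", c("5 and 6", "7", "8", "9", "10 and 11"))
#' @export
covariate_schema <- function(name, kind = c("ordinal", "nominal"), levels,
                             missing_label = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a single non-empty string.")
  }
  levels <- as.character(levels)
  if (length(levels) < 1L || anyDuplicated(levels) || any(!nzchar(levels))) {
    abort(sprintf("covariate '%s': levels must be unique and non-empty.", name))
  }
  if (kind == "ordinal" && length(levels) < 2L) {
    abort(sprintf("covariate '%s': ordinal covariates need >= 2 ordered levels.", name))
  }
  if (!is.null(missing_label) && missing_label %in% levels) {
    abort(sprintf("covariate '%s': missing_label collides with a declared level.", name))
  }
  structure(
    list(name = name, kind = kind, levels = levels,
         missing_label = missing_label),
    class = "covariate_schema"
  )
}

#' Declare a health outcome
#'
#' @param name Column name in the survey table.
#' @param measure `"continuous"` (bounded score) or `"binary"` (0/1).
#' @param range Numeric `c(min, max)` for continuous outcomes.
#' @param disadvantage_sign `+1` or `-1`. The reported gap is
#'   `disadvantage_sign * (group2 - group1)`, so that the inequality of
#'   interest is positive. For a positively-coded score on which the
#'   reference group scores higher (e.g. a positive psychosomatic health
#'   score where males score above females), use `-1`.
#' @return An object of class `outcome_spec`.
#' @examples
#' outcome_spec("psychosomatic", "continuous", range = c(0, 40),
#'              disadvantage_sign = -1)
#' outcome_spec("depression", "binary")
#' @export
outcome_spec <- function(name, measure = c("continuous", "binary"),
                         range = NULL, disadvantage_sign = 1) {
  measure <- match.arg(measure)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a single non-empty string.")
  }
  if (measure == "continuous") {
    if (is.null(range) || length(range) != 2L || !is.numeric(range) ||
        anyNA(range) || range[1] >= range[2]) {
      abort(sprintf("outcome '%s': continuous outcomes need range = c(min, max).", name))
    }
    range <- as.numeric(range)
  } else {
    range <- c(0, 1)
  }
  if (!disadvantage_sign %in% c(-1, 1)) {
    abort(sprintf("outcome '%s': disadvantage_sign must be +1 or -1.", name))
  }
  structure(
    list(name = name, measure = measure, range = range,
         disadvantage_sign = as.numeric(disadvantage_sign)),
    class = "outcome_spec"
  )
}

#' Declare the full survey schema
#'
#' Binds the two-level contrast column (the "treatment" of the differential
#' effect search, e.g. gender), the covariates eligible for splitting, and
#' the outcomes.
#'
#' @param contrast Name of the contrast column.
#' @param contrast_levels Character vector of exactly two labels; the first
#'   is the reference group (group 1). Gap signs follow
#'   [outcome_spec()]'s `disadvantage_sign` applied to group2 - group1.
#' @param covariates List of [covariate_schema()] objects.
#' @param outcomes List of [outcome_spec()] objects.
#' @return An object of class `survey_schema`.
#' @export
survey_schema <- function(contrast, contrast_levels, covariates, outcomes) {
  if (length(contrast_levels) != 2L || anyDuplicated(contrast_levels)) {
    abort("`contrast_levels` must be two distinct labels (reference first).")
  }
  covariates <- check_schema_list(covariates, "covariate_schema")
  outcomes <- check_schema_list(outcomes, "outcome_spec")
  nm <- c(contrast, names(covariates), names(outcomes))
  if (anyDuplicated(nm)) {
    abort("contrast, covariate and outcome names must all be distinct.")
  }
  structure(
    list(contrast = contrast, contrast_levels = as.character(contrast_levels),
         covariates = covariates, outcomes = outcomes),
    class = "survey_schema"
  )
}

check_schema_list <- function(x, cls) {
  if (!is.list(x) || length(x) == 0L ||
      !all(vapply(x, inherits, logical(1), cls))) {
    abort(sprintf("expected a non-empty list of %s objects.", cls))
  }
  names(x) <- vapply(x, `[[`, character(1), "name")
  x
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("<survey_schema>\n")
  cat(sprintf("  contrast: %s (%s vs %s)\n", x$contrast,
              x$contrast_levels[1], x$contrast_levels[2]))
  for (cv in x$covariates) {
    cat(sprintf("  covariate %s [%s]: %s\n", cv$name, cv$kind,
                paste(cv$levels, collapse = " | ")))
  }
  for (oc in x$outcomes) {
    cat(sprintf("  outcome %s [%s, sign %+d]\n", oc$name, oc$measure,
                as.integer(oc$disadvantage_sign)))
  }
  invisible(x)
}

#' Read a survey schema from YAML or JSON
#'
#' The file mirrors the constructor fields: top-level `contrast`,
#' `contrast_levels`, then `covariates` and `outcomes` as lists of records
#' with the fields of [covariate_schema()] / [outcome_spec()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [survey_schema()] object.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(sprintf("schema file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  schema_from_list(raw)
}

schema_from_list <- function(raw) {
  covs <- lapply(raw$covariates, function(cv) {
    covariate_schema(cv$name, cv$kind, unlist(cv$levels),
                     missing_label = cv$missing_label)
  })
  outs <- lapply(raw$outcomes, function(oc) {
    outcome_spec(oc$name, oc$measure,
                 range = if (!is.null(oc$range)) unlist(oc$range),
                 disadvantage_sign = oc$disadvantage_sign %||% 1)
  })
  survey_schema(raw$contrast, unlist(raw$contrast_levels), covs, outs)
}

schema_to_list <- function(schema) {
  list(
    contrast = schema$contrast,
    contrast_levels = schema$contrast_levels,
    covariates = lapply(unname(schema$covariates), function(cv) {
      out <- list(name = cv$name, kind = cv$kind, levels = cv$levels)
      if (!is.null(cv$missing_label)) out$missing_label <- cv$missing_label
      out
    }),
    outcomes = lapply(unname(schema$outcomes), function(oc) {
      list(name = oc$name, measure = oc$measure, range = oc$range,
           disadvantage_sign = oc$disadvantage_sign)
    })
  )
}

#' Write a survey schema to YAML
#'
#' @param schema A [survey_schema()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "survey_schema"))
  yaml::write_yaml(schema_to_list(schema), path)
  invisible(path)
}

resolve_outcome <- function(schema, outcome) {
  if (inherits(outcome, "outcome_spec")) return(outcome)
  if (is.character(outcome) && length(outcome) == 1L) {
    spec <- schema$outcomes[[outcome]]
    if (is.null(spec)) {
      abort(sprintf("unknown outcome '%s'; declared: %s", outcome,
                    paste(names(schema$outcomes), collapse = ", ")))
    }
    return(spec)
  }
  abort("`outcome` must be an outcome name or an outcome_spec.")
}

resolve_covariates <- function(schema, covariates = NULL) {
  if (is.null(covariates)) return(schema$covariates)
  if (is.character(covariates)) {
    bad <- setdiff(covariates, names(schema$covariates))
    if (length(bad)) {
      abort(sprintf("unknown covariate(s): %s", paste(bad, collapse = ", ")))
    }
    return(schema$covariates[covariates])
  }
  check_schema_list(covariates, "covariate_schema")
}
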