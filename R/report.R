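# stderr logger; level threshold settable via set_log_level()
the <- new.env(parent = emptyenv())
the$log_level <- "info"

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L, quiet = 5L)

#' Set the package's logging threshold
#'
#' Messages at or above the threshold are written to stderr.
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`,
#'   `"quiet"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "error", "quiet")) {
  level <- match.arg(level)
  old <- the$log_level
  the$log_level <- level
  invisible(old)
}

log_at <- function(level, fmt, ...) {
  if (log_levels[[level]] >= log_levels[[the$log_level]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
}
log_info <- function(fmt, ...) log_at("info", fmt, ...)
log_debug <- function(fmt, ...) log_at("debug", fmt, ...)

#' Structured run report of a fit
#'
#' Assembles the JSON-ready report: outcome, overall effect, every
#' promising subgroup with its rule in canonical text form, per-group
#' sizes and summaries, CI and adjusted p-value, plus a configuration
#' echo, the centering offset used, the seed and the package version.
#'
#' @param fit A `sides_fit` from [sides()].
#' @return A named list (class `run_report`).
#' @export
run_report <- function(fit) {
  stopifnot(inherits(fit, "sides_fit"))
  sub <- tidy(fit)
  structure(list(
    outcome = fit$outcome$name,
    measure = fit$outcome$measure,
    n = fit$n,
    offset_D = fit$offset$D,
    overall = list(
      diff = fit$overall$diff, se = fit$overall$se,
      ci_low = fit$overall$ci_low, ci_high = fit$overall$ci_high,
      summary1 = fit$overall$summary1, summary2 = fit$overall$summary2,
      n1 = fit$overall$n1, n2 = fit$overall$n2
    ),
    subgroups = lapply(seq_len(nrow(sub)), function(i) {
      list(
        rule = sub$rule[i], depth = sub$depth[i],
        n1 = sub$n1[i], n2 = sub$n2[i],
        summary1 = sub$summary1[i], summary2 = sub$summary2[i],
        diff = sub$diff[i], se = sub$se[i],
        ci_low = sub$ci_low[i], ci_high = sub$ci_high[i],
        p_split = sub$p_split[i], adjusted_p = sub$adjusted_p[i]
      )
    }),
    config = list(
      M = fit$config$M, L = fit$config$L, gamma = fit$config$gamma,
      min_node = fit$config$min_node, min_events = fit$config$min_events,
      alpha = fit$config$alpha, B = fit$null$B
    ),
    seed = fit$null$seed,
    version = as.character(packageVersion("sidesearch"))
  ), class = "run_report")
}

#' Write a run report as JSON (plus optional subgroup CSV)
#'
#' @param report A `run_report` (or a `sides_fit`, converted on the fly).
#' @param path JSON output path.
#' @param csv_path Optional path for a flat CSV of the subgroup table.
#' @param fit The fit, required when `csv_path` is given and `report` is
#'   not a `sides_fit`.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path, csv_path = NULL, fit = NULL) {
  if (inherits(report, "sides_fit")) {
    fit <- report
    report <- run_report(report)
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    if (is.null(fit)) abort("writing the subgroup CSV needs the fit object.")
    readr::write_csv(dplyr::select(tidy(fit), -"rule_obj"), csv_path, na = "")
  }
  invisible(path)
}

#' Validate a run report against the shipped JSON schema
#'
#' Checks the structural contract published in
#' `inst/schema/run-report.schema.json`: required properties, their JSON
#' types, and the per-subgroup required fields.
#'
#' @param report A `run_report`, or a path to a report JSON file.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_run_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  schema <- jsonlite::read_json(
    system.file("schema", "run-report.schema.json", package = "sidesearch"),
    simplifyVector = FALSE)
  check_json_object(unclass(report), schema, "report")
  invisible(TRUE)
}

json_type_ok <- function(x, type) {
  switch(type,
    number = is.numeric(x) && length(x) == 1L,
    integer = is.numeric(x) && length(x) == 1L && x == round(x),
    string = is.character(x) && length(x) == 1L,
    array = is.list(x) || (is.vector(x) && length(x) != 1L) || is.numeric(x),
    object = is.list(x) && !is.null(names(x)),
    FALSE)
}

check_json_object <- function(x, schema, where) {
  for (nm in unlist(schema$required)) {
    if (is.null(x[[nm]])) {
      abort(sprintf("%s: missing required property '%s'.", where, nm))
    }
  }
  for (nm in names(schema$properties)) {
    if (is.null(x[[nm]])) next
    prop <- schema$properties[[nm]]
    if (!is.null(prop$type) && !json_type_ok(x[[nm]], prop$type)) {
      abort(sprintf("%s: property '%s' is not of JSON type '%s'.",
                    where, nm, prop$type))
    }
    if (identical(prop$type, "object") &&
        (!is.null(prop$required) || !is.null(prop$properties))) {
      check_json_object(x[[nm]], prop, sprintf("%s$%s", where, nm))
    }
    if (identical(prop$type, "array") && !is.null(prop$items$properties)) {
      for (i in seq_along(x[[nm]])) {
        check_json_object(x[[nm]][[i]], prop$items,
                          sprintf("%s$%s[%d]", where, nm, i))
      }
    }
  }
  invisible(TRUE)
}
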