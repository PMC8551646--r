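#' Construct a validated survey table
#'
#' Coerces a data frame to the package's tabular data model: the contrast
#' column becomes a factor with the two declared levels (reference first),
#' covariates become factors over their declared levels (the declared
#' `missing_label` maps to `NA`), and outcomes are validated numerically.
#'
#' @param data A data frame with one row per respondent.
#' @param schema A [survey_schema()].
#' @return A tibble of class `survey_table` carrying the schema as an
#'   attribute.
#' @export
survey_table <- function(data, schema) {
  stopifnot(inherits(schema, "survey_schema"))
  data <- tibble::as_tibble(data)
  need <- c(schema$contrast, names(schema$covariates), names(schema$outcomes))
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("unknown column(s): table lacks %s",
                  paste(missing_cols, collapse = ", ")))
  }

  cvals <- as.character(data[[schema$contrast]])
  cvals[!is.na(cvals) & !nzchar(cvals)] <- NA
  bad <- which(!is.na(cvals) & !cvals %in% schema$contrast_levels)
  if (length(bad)) {
    abort(sprintf(
      "column '%s', record %d: undeclared contrast level '%s'",
      schema$contrast, bad[1], cvals[bad[1]]))
  }
  seen <- unique(cvals[!is.na(cvals)])
  if (length(seen) != 2L) {
    abort(sprintf("column '%s': expected both contrast levels present, found %s",
                  schema$contrast,
                  if (length(seen)) paste(seen, collapse = ", ") else "none"))
  }
  data[[schema$contrast]] <- factor(cvals, levels = schema$contrast_levels)

  for (cv in schema$covariates) {
    v <- as.character(data[[cv$name]])
    v[!is.na(v) & !nzchar(v)] <- NA
    if (!is.null(cv$missing_label)) v[!is.na(v) & v == cv$missing_label] <- NA
    bad <- which(!is.na(v) & !v %in% cv$levels)
    if (length(bad)) {
      abort(sprintf("column '%s', record %d: undeclared level '%s'",
                    cv$name, bad[1], v[bad[1]]))
    }
    data[[cv$name]] <- factor(v, levels = cv$levels)
  }

  for (oc in schema$outcomes) {
    v <- data[[oc$name]]
    if (is.character(v)) v[!is.na(v) & !nzchar(v)] <- NA
    v <- suppressWarnings(as.numeric(v))
    chk <- !is.na(v)
    if (oc$measure == "binary") {
      bad <- which(chk & !v %in% c(0, 1))
      if (length(bad)) {
        abort(sprintf("column '%s', record %d: binary outcome value %s not in {0,1}",
                      oc$name, bad[1], format(v[bad[1]])))
      }
    } else {
      bad <- which(chk & (v < oc$range[1] | v > oc$range[2]))
      if (length(bad)) {
        abort(sprintf(
          "column '%s', record %d: value %s outside declared range [%s, %s]",
          oc$name, bad[1], format(v[bad[1]]),
          format(oc$range[1]), format(oc$range[2])))
      }
    }
    data[[oc$name]] <- v
  }

  new_survey_table(data, schema)
}

new_survey_table <- function(data, schema) {
  structure(data,
            schema = schema,
            class = c("survey_table", class(tibble::tibble())))
}

#' Retrieve the schema attached to a survey table
#' @param table A `survey_table`.
#' @return The [survey_schema()].
#' @export
table_schema <- function(table) {
  schema <- attr(table, "schema", exact = TRUE)
  if (is.null(schema)) abort("not a survey_table: no attached schema.")
  schema
}

#' @export
print.survey_table <- function(x, ...) {
  schema <- table_schema(x)
  n_by <- table(x[[schema$contrast]])
  cat(sprintf("<survey_table> %d records (%s)\n", nrow(x),
              paste(sprintf("%s: %d", names(n_by), n_by), collapse = ", ")))
  NextMethod()
}

#' Read a survey table from CSV
#'
#' Expects an RFC-4180 CSV with a header row. Cells are validated against
#' the schema: undeclared categorical levels and out-of-range outcome
#' values raise errors naming the record and column; empty cells and the
#' declared `missing_label` are read as missing.
#'
#' @param path CSV path.
#' @param schema A [survey_schema()], or a path to a schema YAML/JSON file.
#' @return A `survey_table`.
#' @export
read_survey <- function(path, schema) {
  if (is.character(schema)) schema <- read_schema(schema)
  if (!file.exists(path)) abort(sprintf("data file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  survey_table(raw, schema)
}

#' Write a survey table to CSV
#'
#' Missing values are written as empty cells, so a written table re-read
#' with [read_survey()] round-trips exactly.
#'
#' @param table A `survey_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  schema <- table_schema(table)
  out <- as.data.frame(table)
  for (nm in c(schema$contrast, names(schema$covariates))) {
    out[[nm]] <- as.character(out[[nm]])
  }
  readr::write_csv(tibble::as_tibble(out), path, na = "")
  invisible(path)
}
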