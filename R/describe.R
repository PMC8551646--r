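#' Descriptive covariate summary by contrast group
#'
#' One row per covariate level with per-group counts and percentages,
#' plus a `Missing` row per covariate with missing counts. Percentages
#' use the non-missing denominator within each contrast group and are
#' rounded to one decimal, the convention of survey descriptive tables.
#'
#' @param table A `survey_table`.
#' @param covariates Optional character vector restricting/ordering the
#'   covariates summarised; defaults to all declared covariates.
#' @return A tibble with columns `covariate`, `level`, `count_group1`,
#'   `pct_group1`, `count_group2`, `pct_group2`; the contrast labels are
#'   attached as the `contrast_levels` attribute. `Missing` rows carry
#'   `NA` percentages.
#' @export
describe_survey <- function(table, covariates = NULL) {
  schema <- table_schema(table)
  covs <- resolve_covariates(schema, covariates)
  g <- table[[schema$contrast]]

  out <- purrr::map_dfr(covs, function(cv) {
    v <- table[[cv$name]]
    counts <- table(v, g)                       # declared levels x 2 groups
    n_miss <- tapply(is.na(v), g, sum)
    denom <- colSums(counts)
    pct <- sweep(counts, 2, pmax(denom, 1L), "/") * 100
    lvl <- tibble::tibble(
      covariate = cv$name,
      level = rownames(counts),
      count_group1 = as.integer(counts[, 1]),
      pct_group1 = round(unname(pct[, 1]), 1),
      count_group2 = as.integer(counts[, 2]),
      pct_group2 = round(unname(pct[, 2]), 1)
    )
    dplyr::bind_rows(lvl, tibble::tibble(
      covariate = cv$name, level = "Missing",
      count_group1 = as.integer(n_miss[1]), pct_group1 = NA_real_,
      count_group2 = as.integer(n_miss[2]), pct_group2 = NA_real_
    ))
  })
  structure(out, contrast_levels = schema$contrast_levels)
}

#' Write a descriptive summary to CSV
#'
#' @param description Output of [describe_survey()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_description <- function(description, path) {
  readr::write_csv(description, path, na = "")
  invisible(path)
}
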