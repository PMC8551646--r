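#' Default schema for an adolescent-survey-like dataset
#'
#' Mirrors the structure of the Canadian HBSC (Health Behaviour in
#' School-aged Children) 2017-18 cycle used in intersectional analyses of
#' adolescent mental health: a male/female contrast (males as reference),
#' eight social-location covariates, and three mental-health outcomes.
#' Grade, urban/rural size class, family-SES quintile, relative affluence
#' and years-in-Canada are ordinal; family structure, religious
#' involvement and racial/cultural background are nominal.
#'
#' The positive psychosomatic health score is nominally coded 0-32
#' (eight symptom items, reverse-coded), but published per-group means
#' for this cohort exceed 32, so the default spec admits `[0, 40]`; pass
#' a modified [outcome_spec()] to tighten it. Its `disadvantage_sign` is
#' -1: males score higher, so the male-minus-female gap is the positive
#' direction. The two binary outcomes (depression symptoms, diagnosed
#' mental illness) use +1: female-minus-male.
#'
#' @return A [survey_schema()].
#' @export
default_survey_schema <- function() {
  survey_schema(
    contrast = "gender",
    contrast_levels = c("male", "female"),
    covariates = list(
      covariate_schema("grade", "ordinal",
                       c("5 and 6", "7", "8", "9", "10 and 11")),
      covariate_schema("urban_rural", "ordinal",
                       c("Rural", "Small", "Medium", "Large")),
      covariate_schema("ses_quintile", "ordinal",
                       c("Q1", "Q2", "Q3", "Q4", "Q5")),
      covariate_schema("family_structure", "nominal",
                       c("Mother and father", "Mother and partner",
                         "Mother only", "Father and partner", "Father only",
                         "Other")),
      covariate_schema("immigration", "ordinal",
                       c("Immigrated <5 years ago", "Immigrated 5+ years ago",
                         "Born in Canada")),
      covariate_schema("affluence", "ordinal", c("High", "Average", "Low")),
      covariate_schema("religious", "nominal", c("Yes", "No")),
      covariate_schema("ethnicity", "nominal",
                       c("White", "Black", "Indigenous", "East Asian",
                         "West Asian and Arab", "Other"))
    ),
    outcomes = list(
      outcome_spec("psychosomatic", "continuous", range = c(0, 40),
                   disadvantage_sign = -1),
      outcome_spec("depression", "binary"),
      outcome_spec("diagnosis", "binary")
    )
  )
}

#' The rule planted by the default generator
#'
#' Upper-level grades intersected with low relative affluence -- the
#' "older adolescents of low affluence" social location on which all
#' three default outcome models carry an excess gap.
#'
#' @return A [subgroup_rule()]: `grade>=9 & affluence>=Low`.
#' @export
default_planted_rule <- function() {
  subgroup_rule(condition("grade", "ge", "9"),
                condition("affluence", "ge", "Low"))
}

#' Default calibrated generator configuration
#'
#' Emulates the covariate structure and outcome levels of the 2017-18
#' Canadian HBSC analysis sample of 10,349 males and 10,872 females aged
#' 11-15: per-gender covariate marginals and missingness matching the
#' published descriptive table, and outcome models calibrated so observed
#' summaries reproduce the published values -- psychosomatic means
#' 32.9 (males) / 29.2 (females) overall and 31.6 / 26.6 among older
#' low-affluence adolescents (gaps 3.7 and 5.0 on the score scale);
#' depression prevalences 22.5% / 40.1% overall and 29.4% / 53.7% in the
#' planted subgroup (gaps 17.6 and 24.3 points); diagnosed mental illness
#' 2.8% / 9.3% overall and 4.0% / 16.5% in the subgroup (gaps 6.6 and
#' 12.6 points). The planted rule is [default_planted_rule()]. The
#' psychosomatic residual sd defaults to 6.5 score points, consistent
#' with the published confidence-interval widths at these sample sizes.
#'
#' @param n_per_group Length-2 counts (males, females); defaults to the
#'   full cohort sizes `c(10349, 10872)`.
#' @param sd_psych Residual sd of the psychosomatic score.
#' @param seed Default generation seed.
#' @return A [generator_config()].
#' @export
default_survey_config <- function(n_per_group = c(10349, 10872),
                                  sd_psych = 6.5, seed = 1) {
  schema <- default_survey_schema()
  rule <- default_planted_rule()
  marginals <- list(
    grade = cbind(c(.197, .207, .204, .222, .170),
                  c(.179, .213, .208, .222, .177)),
    urban_rural = cbind(c(.043, .526, .175, .257),
                        c(.040, .512, .174, .274)),
    ses_quintile = cbind(c(.175, .207, .200, .200, .218),
                         c(.190, .206, .194, .197, .213)),
    family_structure = cbind(c(.723, .048, .153, .010, .032, .034),
                             c(.706, .062, .160, .013, .028, .032)),
    immigration = cbind(c(.072, .184, .744), c(.067, .149, .784)),
    affluence = cbind(c(.557, .358, .085), c(.512, .396, .092)),
    religious = cbind(c(.241, .759), c(.257, .743)),
    ethnicity = cbind(c(.666, .036, .078, .060, .014, .146),
                      c(.661, .034, .077, .059, .014, .156))
  )
  marginals <- lapply(marginals, function(m) sweep(m, 2, colSums(m), "/"))
  # per-gender missing counts over cohort totals (10,349 / 10,872)
  missing_rates <- list(
    grade = c(1 / 10349, 0),
    ses_quintile = c(2138 / 10349, 1749 / 10872),
    family_structure = c(277 / 10349, 208 / 10872),
    immigration = c(649 / 10349, 728 / 10872),
    affluence = c(1494 / 10349, 1275 / 10872),
    religious = c(558 / 10349, 413 / 10872),
    ethnicity = c(182 / 10349, 176 / 10872)
  )
  models <- list(
    outcome_model(schema$outcomes$psychosomatic,
                  overall = c(32.9, 29.2), subgroup = c(31.6, 26.6),
                  rule = rule, sd = sd_psych),
    outcome_model(schema$outcomes$depression,
                  overall = c(.225, .401), subgroup = c(.294, .537),
                  rule = rule),
    outcome_model(schema$outcomes$diagnosis,
                  overall = c(.028, .093), subgroup = c(.040, .165),
                  rule = rule)
  )
  generator_config(schema, n_per_group, marginals, models,
                   missing_rates = missing_rates, seed = seed)
}

#' Read a generator configuration from YAML
#'
#' The file mirrors the constructor inputs: `schema` (as in
#' [read_schema()]), `n_per_group`, `marginals` (per covariate, a vector
#' or per-group list of vectors), `models` (with `outcome`, `overall`,
#' optional `subgroup` + `rule`, `sd`), `missing_rates`, `seed`. A
#' bundled file reproducing [default_survey_config()] ships at
#' `system.file("extdata", "default-config.yaml", package = "sidesearch")`.
#'
#' @param path YAML path.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  schema <- schema_from_list(raw$schema)
  marginals <- lapply(raw$marginals, function(m) {
    if (is.list(m)) do.call(cbind, lapply(m, unlist)) else unlist(m)
  })
  models <- lapply(raw$models, function(md) {
    rule <- if (!is.null(md$rule)) {
      subgroup_rule(lapply(md$rule, function(cd) {
        condition(cd$covariate, cd$op, unlist(cd$value))
      }))
    }
    outcome_model(schema$outcomes[[md$outcome]],
                  overall = unlist(md$overall),
                  subgroup = if (!is.null(md$subgroup)) unlist(md$subgroup),
                  rule = rule, sd = md$sd,
                  missing_rate = md$missing_rate %||% 0)
  })
  generator_config(schema, unlist(raw$n_per_group), marginals, models,
                   missing_rates = lapply(raw$missing_rates %||% list(), unlist),
                   seed = raw$seed %||% 1)
}

#' Write a generator configuration to YAML
#'
#' @param config A [generator_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  raw <- list(
    schema = schema_to_list(config$schema),
    n_per_group = config$n_per_group,
    marginals = lapply(config$marginals, function(m) {
      list(as.numeric(m[, 1]), as.numeric(m[, 2]))
    }),
    models = lapply(unname(config$models), function(mod) {
      out <- list(outcome = mod$spec$name, overall = mod$overall)
      if (!is.null(mod$subgroup)) {
        out$subgroup <- mod$subgroup
        out$rule <- lapply(mod$rule$conditions, function(cd) {
          list(covariate = cd$covariate, op = cd$op, value = cd$value)
        })
      }
      if (!is.null(mod$sd)) out$sd <- mod$sd
      if (any(mod$missing_rate > 0)) out$missing_rate <- mod$missing_rate
      out
    }),
    missing_rates = config$missing_rates,
    seed = config$seed
  )
  yaml::write_yaml(raw, path, precision = 12)
  invisible(path)
}
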