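test_that("CSV survey tables parse, validate and round-trip", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "grp,grade,colour,score,event",
    "a,5,red,1.5,0",
    "b,7,green,2.5,1",
    "a,9,Missing,0.0,1",
    "b,11,blue,-3.25,0",
    "a,7,,4.0,",
    "b,9,red,2.0,1"
  ), csv)
  tab <- read_survey(csv, tiny_schema())
  expect_s3_class(tab, "survey_table")
  expect_equal(nrow(tab), 6L)
  # declared missing label and empty cells both land as NA
  expect_equal(sum(is.na(tab$colour)), 2L)
  expect_true(is.na(tab$event[5]))

  out <- tempfile(fileext = ".csv")
  write_survey(tab, out)
  again <- read_survey(out, tiny_schema())
  expect_equal(as.data.frame(again), as.data.frame(tab))
})

test_that("schema violations raise errors naming the record and column", {
  df <- data.frame(grp = c("a", "b"), grade = c("5", "13"),
                   colour = "red", score = 0, event = 0)
  expect_error(survey_table(df, tiny_schema()), "grade.*record 2.*13")
  df2 <- data.frame(grp = c("a", "b", "c"), grade = "5", colour = "red",
                    score = 0, event = 0)
  expect_error(survey_table(df2, tiny_schema()), "contrast level 'c'")
  df3 <- data.frame(grp = c("a", "b"), grade = "5", colour = "red",
                    score = c(0, 101), event = 0)
  expect_error(survey_table(df3, tiny_schema()), "score.*record 2.*range")
  df4 <- data.frame(grp = c("a", "b"), grade = "5", colour = "red",
                    score = 0, event = c(0, 2))
  expect_error(survey_table(df4, tiny_schema()), "event.*record 2")
  expect_error(survey_table(data.frame(grp = c("a", "b")), tiny_schema()),
               "unknown column")
  df5 <- data.frame(grp = "a", grade = "5", colour = "red",
                    score = 0, event = 0)
  expect_error(survey_table(df5, tiny_schema()), "both contrast levels")
})

test_that("schema YAML round-trips through read_schema/write_schema", {
  path <- tempfile(fileext = ".yaml")
  write_schema(tiny_schema(), path)
  sch <- read_schema(path)
  expect_equal(sch, tiny_schema())
})

test_that("apply_rule filters by conjunction with complete-case handling", {
  sch <- tiny_schema()
  df <- data.frame(
    grp = rep(c("a", "b"), 10),
    grade = rep(c("7", "9"), each = 10),
    colour = rep(c("red", "green", NA, "blue"), 5),
    score = rnorm(20), event = rbinom(20, 1, .5)
  )
  tab <- survey_table(df, sch)

  expect_equal(nrow(apply_rule(tab, subgroup_rule())), 20L)  # empty rule
  half <- apply_rule(tab, subgroup_rule(condition("grade", "ge", "9")))
  expect_equal(nrow(half), 10L)

  # records missing a rule covariate belong to neither side
  red <- apply_rule(tab, subgroup_rule(condition("colour", "in", "red")))
  notred <- apply_rule(tab, subgroup_rule(
    condition("colour", "in", c("green", "blue"))))
  expect_equal(nrow(red) + nrow(notred), sum(!is.na(df$colour)))
})

test_that("apply_rule matches a brute-force row scan and is monotone", {
  cfg <- default_survey_config(n_per_group = c(600, 600))
  tab <- generate_survey(cfg, seed = 42)
  rule <- subgroup_rule(condition("affluence", "ge", "Low"),
                        condition("grade", "ge", "9"))
  got <- nrow(apply_rule(tab, rule))
  # independent row scan on the raw columns
  aff <- as.character(tab$affluence)
  grd <- as.character(tab$grade)
  manual <- sum(!is.na(aff) & aff == "Low" &
                !is.na(grd) & grd %in% c("9", "10 and 11"))
  expect_equal(got, manual)

  # adding a condition never increases n (random condition chains)
  withr::with_seed(7, {
    for (i in 1:20) {
      covs <- sample(names(cfg$schema$covariates), 3)
      conds <- list()
      prev <- nrow(tab)
      for (cv in covs) {
        sc <- cfg$schema$covariates[[cv]]
        cond <- if (sc$kind == "ordinal") {
          condition(cv, "le", sample(sc$levels[-length(sc$levels)], 1))
        } else {
          condition(cv, "in", sample(sc$levels, sample(length(sc$levels) - 1, 1)))
        }
        conds <- c(conds, list(cond))
        n <- nrow(apply_rule(tab, subgroup_rule(conds)))
        expect_lte(n, prev)
        prev <- n
      }
    }
  })
})

test_that("rule rendering and de-duplication keys are canonical", {
  r <- subgroup_rule(condition("grade", "ge", "9"),
                     condition("affluence", "in", "Low"))
  expect_equal(format(r), "grade>=9 & affluence in {Low}")
  expect_equal(format(subgroup_rule()), "<all records>")
  sch <- default_survey_schema()
  r2 <- subgroup_rule(condition("affluence", "in", "Low"),
                      condition("grade", "ge", "9"))
  expect_equal(sidesearch:::rule_key(r, sch), sidesearch:::rule_key(r2, sch))
  # subset order never matters; a subset and its complement select
  # different records and must keep distinct keys
  a <- subgroup_rule(condition("ethnicity", "in", c("White", "Black")))
  a2 <- subgroup_rule(condition("ethnicity", "in", c("Black", "White")))
  b <- subgroup_rule(condition("ethnicity", "in",
                               c("Indigenous", "East Asian",
                                 "West Asian and Arab", "Other")))
  expect_equal(sidesearch:::rule_key(a, sch), sidesearch:::rule_key(a2, sch))
  expect_false(sidesearch:::rule_key(a, sch) == sidesearch:::rule_key(b, sch))
  expect_error(subgroup_rule(condition("grade", "ge", "9"),
                             condition("grade", "le", "7")),
               "at most one condition per covariate")
})

test_that("describe_survey reproduces published-table percentage conventions", {
  # grade counts with one missing male record: 2037/10348 -> 19.7%
  male_grade <- rep(c("5 and 6", "7", "8", "9", "10 and 11", NA),
                    c(2037, 2143, 2114, 2295, 1759, 1))
  female_grade <- rep(c("5 and 6", "7", "8", "9", "10 and 11"),
                      c(1949, 2315, 2264, 2415, 1929))
  male_rel <- rep(c("Yes", "No", NA), c(2359, 7432, 558))
  female_rel <- rep(c("Yes", "No", NA), c(2693, 7766, 413))
  sch <- survey_schema(
    "gender", c("male", "female"),
    covariates = list(
      covariate_schema("grade", "ordinal",
                       c("5 and 6", "7", "8", "9", "10 and 11")),
      covariate_schema("religious", "nominal", c("Yes", "No"))
    ),
    outcomes = list(outcome_spec("y", "binary"))
  )
  df <- data.frame(
    gender = rep(c("male", "female"), c(10349, 10872)),
    grade = c(male_grade, female_grade),
    religious = c(male_rel, female_rel),
    y = 0
  )
  d <- describe_survey(survey_table(df, sch))

  g56 <- d[d$covariate == "grade" & d$level == "5 and 6", ]
  expect_equal(g56$count_group1, 2037L)
  expect_equal(g56$pct_group1, 19.7)
  expect_equal(g56$pct_group2, 17.9)
  rel <- d[d$covariate == "religious" & d$level == "Yes", ]
  expect_equal(rel$pct_group1, 24.1)
  expect_equal(rel$pct_group2, 25.7)
  miss <- d[d$covariate == "religious" & d$level == "Missing", ]
  expect_equal(miss$count_group1, 558L)

  # percentages sum to 100 within rounding slack, per covariate and group
  sums <- stats::aggregate(cbind(pct_group1, pct_group2) ~ covariate,
                           data = d[d$level != "Missing", ], FUN = sum)
  expect_true(all(abs(sums$pct_group1 - 100) <= 0.2))
  expect_true(all(abs(sums$pct_group2 - 100) <= 0.2))
})

test_that("a single-level covariate with no missing yields 100.0", {
  sch <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(covariate_schema("only", "nominal", c("x", "y"))),
    outcomes = list(outcome_spec("e", "binary"))
  )
  df <- data.frame(grp = rep(c("a", "b"), 5), only = "x", e = 0)
  d <- describe_survey(survey_table(df, sch))
  expect_equal(d$pct_group1[d$level == "x"], 100.0)
})

test_that("generated tables written to CSV re-read identically", {
  cfg <- default_survey_config(n_per_group = c(250, 250))
  tab <- generate_survey(cfg, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_survey(tab, path)
  again <- read_survey(path, cfg$schema)
  expect_equal(as.data.frame(again), as.data.frame(tab))
})
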