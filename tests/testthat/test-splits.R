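test_that("enumerate_splits counts partitions correctly", {
  cfg <- default_survey_config(n_per_group = c(2000, 2000))
  tab <- generate_survey(cfg, seed = 3)
  expect_length(enumerate_splits(tab, "grade"), 4L)       # 5 ordered levels
  expect_length(enumerate_splits(tab, "religious"), 1L)   # binary: forced
  expect_length(enumerate_splits(tab, "ethnicity"), 31L)  # 2^(6-1) - 1

  # nominal with 4 observed levels -> 7 bipartitions
  sch <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(covariate_schema("c", "nominal", letters[1:4])),
    outcomes = list(outcome_spec("y", "binary"))
  )
  df <- data.frame(grp = rep(c("a", "b"), 8), c = rep(letters[1:4], 4), y = 0)
  expect_length(enumerate_splits(survey_table(df, sch), "c"), 7L)

  # single observed level -> no usable split
  df1 <- data.frame(grp = rep(c("a", "b"), 8), c = "a", y = 0)
  expect_length(enumerate_splits(survey_table(df1, sch), "c"), 0L)

  # too many nominal levels is an explicit refusal
  sch13 <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(covariate_schema("c", "nominal", letters[1:13])),
    outcomes = list(outcome_spec("y", "binary"))
  )
  df13 <- data.frame(grp = rep(c("a", "b"), 13), c = rep(letters[1:13], 2),
                     y = 0)
  expect_error(enumerate_splits(survey_table(df13, sch13), "c"),
               "refusing to enumerate")
})

test_that("multiplicity adjustment is Sidak over the candidate count", {
  expect_equal(multiplicity_adjust(0.2, 1), 0.2)          # identity
  expect_equal(multiplicity_adjust(0.01, 4), 1 - 0.99^4)
  padj <- vapply(1:30, function(n) multiplicity_adjust(0.05, n), numeric(1))
  expect_true(all(diff(padj) >= 0))                       # monotone in n
  expect_equal(multiplicity_adjust(1, 50), 1)
  expect_error(multiplicity_adjust(0, 3), "0, 1")
  expect_error(multiplicity_adjust(0.5, 0), ">= 1")
})

# Brute-force oracle: exhaustively score every bipartition with direct
# data-frame arithmetic and pick the minimum criterion value.
oracle_best <- function(tab, covname, outcome, D, sign = 1, min_node = 30,
                        min_events = 5, binary = FALSE) {
  parts <- enumerate_splits(tab, covname)
  df <- as.data.frame(tab)
  df <- df[!is.na(df[[outcome]]), ]
  score_child <- function(cond) {
    sub <- as.data.frame(apply_rule(survey_table(df, table_schema(tab)),
                                    subgroup_rule(cond)))
    y1 <- sub[[outcome]][sub$grp == "a"]
    y2 <- sub[[outcome]][sub$grp == "b"]
    if (binary) {
      se <- sqrt(mean(y1) * (1 - mean(y1)) / length(y1) +
                 mean(y2) * (1 - mean(y2)) / length(y2))
    } else {
      se <- sqrt(var(y1) / length(y1) + var(y2) / length(y2))
    }
    list(z = (sign * (mean(y2) - mean(y1)) - D) / se,
         n1 = length(y1), n2 = length(y2),
         ev = if (binary) min(sum(y1), sum(y2)) else Inf, se = se)
  }
  best <- NULL
  ncand <- 0L
  for (pt in parts) {
    a <- score_child(pt$child1)
    b <- score_child(pt$child2)
    if (min(a$n1, a$n2, b$n1, b$n2) < min_node) next
    if (binary && min(a$ev, b$ev) < min_events) next
    if (!is.finite(a$z) || !is.finite(b$z) || a$se == 0 || b$se == 0) next
    ncand <- ncand + 1L
    p <- min(1, 2 * pnorm(max(a$z, b$z), lower.tail = FALSE))
    if (is.null(best) || p < best$p) {
      best <- list(p = p, z1 = a$z, z2 = b$z,
                   cond = if (a$z >= b$z) pt$child1 else pt$child2)
    }
  }
  if (!is.null(best)) best$ncand <- ncand
  best
}

test_that("best_split equals exhaustive minimisation over all bipartitions", {
  sch <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(
      covariate_schema("ord", "ordinal", as.character(1:6)),
      covariate_schema("nom", "nominal", letters[1:5])
    ),
    outcomes = list(
      outcome_spec("score", "continuous", range = c(-100, 100)),
      outcome_spec("event", "binary")
    )
  )
  for (seed in 1:6) {
    tab <- withr::with_seed(seed, {
      n <- 700
      survey_table(data.frame(
        grp = sample(c("a", "b"), n, replace = TRUE),
        ord = as.character(sample(6, n, replace = TRUE)),
        nom = sample(letters[1:5], n, replace = TRUE),
        score = rnorm(n) + runif(1, -1, 1) * (sample(2, n, TRUE) - 1),
        event = rbinom(n, 1, 0.3)
      ), sch)
    })
    for (cov in c("ord", "nom")) {
      for (oc in c("score", "event")) {
        off <- overall_offset(tab, oc)
        got <- best_split(tab, cov, oc, off)
        want <- oracle_best(tab, cov, oc, off$D, binary = oc == "event")
        if (is.null(want)) {
          expect_null(got)
        } else {
          expect_equal(got$p_split, want$p, tolerance = 1e-12)
          expect_equal(got$n_candidates, want$ncand)
          expect_equal(sort(c(got$z1, got$z2)), sort(c(want$z1, want$z2)),
                       tolerance = 1e-12)
          expect_equal(got$condition$covariate, want$cond$covariate)
          expect_setequal(got$condition$value, want$cond$value)
        }
      }
    }
  }
})

test_that("no admissible partition yields a null best split", {
  tab <- random_bin_table(n = 40, p = 1, seed = 2)
  off <- overall_offset(tab, "score")
  expect_null(best_split(tab, "c1", "score", off, min_node = 30))
})

test_that("covariate ranking is ordered, truncated, and tie-stable", {
  sch <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(
      covariate_schema("u1", "nominal", c("A", "B")),
      covariate_schema("u2", "nominal", c("A", "B")),
      covariate_schema("sig", "ordinal", as.character(1:4))
    ),
    outcomes = list(outcome_spec("score", "continuous", range = c(-100, 100)))
  )
  tab <- withr::with_seed(11, {
    n <- 4000
    u <- sample(c("A", "B"), n, replace = TRUE)
    sig <- sample(4, n, replace = TRUE)
    grp <- sample(c("a", "b"), n, replace = TRUE)
    # strong planted interaction on sig >= 3
    score <- rnorm(n) + (grp == "b") * (1 + 1.0 * (sig >= 3))
    survey_table(data.frame(grp = grp, u1 = u, u2 = u,
                            sig = as.character(sig), score = score), sch)
  })
  off <- overall_offset(tab, "score")
  rk <- rank_covariates(tab, outcome = "score", offset = off, M = 5)
  expect_equal(rk$covariate[1], "sig")          # informative ranked first
  expect_true(all(diff(rk$p_adj) >= 0))
  # duplicated covariates score identically and keep declaration order
  i1 <- which(rk$covariate == "u1")
  i2 <- which(rk$covariate == "u2")
  expect_equal(rk$p_adj[i1], rk$p_adj[i2])
  expect_lt(i1, i2)
  # M truncates; a larger M keeps every usable covariate
  expect_equal(nrow(rank_covariates(tab, outcome = "score", offset = off,
                                    M = 2)), 2L)
  expect_equal(nrow(rank_covariates(tab, outcome = "score", offset = off,
                                    M = 10)), 3L)
  # the multiplicity adjustment is pluggable (here: Bonferroni)
  rkb <- rank_covariates(tab, outcome = "score", offset = off, M = 5,
                         adjust = function(p, n) pmin(1, p * n))
  expect_equal(rkb$p_adj, pmin(1, rkb$p_split * rkb$n_candidates))
})
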