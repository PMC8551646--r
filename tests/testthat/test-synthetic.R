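test_that("generation is seed-reproducible", {
  cfg <- default_survey_config(n_per_group = c(400, 400))
  a <- generate_survey(cfg, seed = 31)
  b <- generate_survey(cfg, seed = 31)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_survey(cfg, seed = 32)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
})

test_that("empirical marginals match the configured marginals", {
  cfg <- default_survey_config(n_per_group = c(50000, 50000))
  cfg$missing_rates <- list()                  # test the sampler directly
  tab <- generate_survey(cfg, seed = 77)
  g <- tab$gender
  for (nm in names(cfg$schema$covariates)) {
    for (grp in 1:2) {
      obs <- table(tab[[nm]][as.integer(g) == grp])
      gof <- suppressWarnings(
        stats::chisq.test(obs, p = cfg$marginals[[nm]][, grp]))
      expect_gt(gof$p.value, 0.001)
    }
  }
})

test_that("missingness lands at the configured per-group rates", {
  cfg <- default_survey_config(n_per_group = c(20000, 20000))
  tab <- generate_survey(cfg, seed = 55)
  g <- as.integer(tab$gender)
  for (nm in names(cfg$missing_rates)) {
    for (grp in 1:2) {
      r <- cfg$missing_rates[[nm]][grp]
      got <- mean(is.na(tab[[nm]][g == grp]))
      tol <- 3 * sqrt(max(r, 1e-4) * (1 - r) / 20000)
      expect_lt(abs(got - r), tol + 1e-3)
    }
  }
})

test_that("planted interactions are recoverable; the null variant is homogeneous", {
  cfg <- default_survey_config(n_per_group = c(40000, 40000))
  tab <- generate_survey(cfg, seed = 13)
  rule <- default_planted_rule()
  # excess gap in the planted cell matches the configured interaction
  for (oc in c("diagnosis", "depression", "psychosomatic")) {
    eff_sub <- group_effect(apply_rule(tab, rule), oc)
    tgt <- cfg$latents[[oc]]$cells_target
    want_gap <- cfg$schema$outcomes[[oc]]$disadvantage_sign *
      (tgt[2, "inside"] - tgt[1, "inside"])
    expect_lt(abs(eff_sub$diff - want_gap), 3 * eff_sub$se)
  }

  # null variant: single-level subgroups all sit near the global gap
  ncfg <- null_config(default_survey_config(n_per_group = c(50000, 50000)))
  ntab <- generate_survey(ncfg, seed = 14)
  off <- overall_offset(ntab, "depression")
  zs <- c()
  for (nm in names(ncfg$schema$covariates)) {
    for (lev in ncfg$schema$covariates[[nm]]$levels) {
      sub <- apply_rule(ntab, subgroup_rule(condition(nm, "in", lev)))
      if (nrow(sub) < 500) next
      zs <- c(zs, centered_z(group_effect(sub, "depression"), off))
    }
  }
  expect_gt(length(zs), 25)
  expect_lte(sum(abs(zs) > 3), 1)          # allow one 3-sigma excursion
})

test_that("binary calibration is exact and continuous calibration inverts clipping", {
  cfg <- default_survey_config()
  # binary: cell probabilities equal the targets by construction
  lat <- cfg$latents$diagnosis
  expect_equal(plogis(lat$latent), lat$cells_target, tolerance = 1e-12)
  # overall mixture recovers the printed overall targets
  mix <- lat$p_in * lat$cells_target[, "inside"] +
    (1 - lat$p_in) * lat$cells_target[, "out"]
  expect_equal(unname(mix), c(.028, .093), tolerance = 1e-9)
  # continuous: clipped-normal mean of the latent equals the target
  latc <- cfg$latents$psychosomatic
  for (i in 1:2) for (j in 1:2) {
    got <- integrate(function(x) {
      pmin(pmax(x, 0), 40) * dnorm(x, latc$latent[i, j], 6.5)
    }, -60, 120)$value
    expect_equal(got, unname(latc$cells_target[i, j]), tolerance = 1e-5)
  }
})

test_that("the bundled config file reproduces the in-code defaults", {
  path <- system.file("extdata", "default-config.yaml", package = "sidesearch")
  cfg <- read_generator_config(path)
  ref <- default_survey_config()
  expect_equal(cfg$marginals, ref$marginals, tolerance = 1e-9)
  expect_equal(cfg$latents, ref$latents, tolerance = 1e-8)
  expect_equal(cfg$n_per_group, ref$n_per_group)
  # and a config written back out re-reads identically
  tmp <- tempfile(fileext = ".yaml")
  write_generator_config(cfg, tmp)
  again <- read_generator_config(tmp)
  expect_equal(again$latents, cfg$latents, tolerance = 1e-10)
})

test_that("the dependence hook induces the conditional distribution", {
  sch <- survey_schema(
    "grp", c("a", "b"),
    covariates = list(
      covariate_schema("ses", "ordinal", c("low", "mid", "high")),
      covariate_schema("aff", "ordinal", c("H", "A", "L"))
    ),
    outcomes = list(outcome_spec("y", "binary"))
  )
  dep <- matrix(c(.1, .3, .6,  .3, .4, .3,  .7, .25, .05), nrow = 3)
  cfg <- generator_config(
    sch, c(30000, 30000),
    marginals = list(ses = c(.3, .4, .3), aff = c(1 / 3, 1 / 3, 1 / 3)),
    models = list(outcome_model(sch$outcomes$y, overall = c(.1, .2))),
    dependence = list(aff = list(parent = "ses", prob = dep))
  )
  tab <- generate_survey(cfg, seed = 8)
  joint <- prop.table(table(tab$aff, tab$ses), margin = 2)
  expect_lt(max(abs(joint - dep)), 0.02)
})

test_that("invalid generator inputs are rejected", {
  sch <- bin_schema(1)
  expect_error(
    generator_config(sch, c(10, 10), marginals = list(c1 = c(.5, .6)),
                     models = list(outcome_model(sch$outcomes$score,
                                                 overall = c(0, 1), sd = 1))),
    "sum to 1")
  expect_error(
    generator_config(sch, c(10, 10), marginals = list(c1 = c(.7, .3)),
                     models = list()),
    "no outcome model")
  expect_error(outcome_model(sch$outcomes$score, overall = c(0, 1)), "sd > 0")
  expect_error(
    outcome_model(outcome_spec("d", "binary"), overall = c(0, .5)),
    "prevalences")
})
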