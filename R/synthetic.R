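#' Outcome model for the synthetic generator
#'
#' Specifies the observed summaries the generated outcome must reproduce:
#' per-group overall values (means for continuous outcomes, prevalences in
#' `[0,1]` for binary ones) and, optionally, per-group values inside a
#' planted subgroup rule, creating a gender-by-subgroup interaction. The
#' generator back-solves the latent cell parameters so that the *observed*
#' summaries hit these targets: in closed form (`qlogis`) for binary
#' outcomes, and by numerically inverting the clipped-normal mean
#' (`uniroot`, tolerance 1e-8) for continuous ones, where clipping to the
#' declared range would otherwise bias the calibration.
#'
#' @param spec An [outcome_spec()].
#' @param overall Length-2 numeric: target observed summaries for
#'   group 1 and group 2 over the whole population.
#' @param subgroup Optional length-2 numeric: targets inside `rule`.
#' @param rule Optional [subgroup_rule()] carrying the planted
#'   interaction.
#' @param sd Residual standard deviation (continuous outcomes).
#' @param missing_rate Probability an outcome value is missing (scalar or
#'   per-group length 2). Default 0.
#' @return An `outcome_model`.
#' @export
outcome_model <- function(spec, overall, subgroup = NULL, rule = NULL,
                          sd = NULL, missing_rate = 0) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (length(overall) != 2L || anyNA(overall)) {
    abort(sprintf("outcome '%s': overall targets must be length-2 numeric.", spec$name))
  }
  if (!is.null(subgroup) && is.null(rule)) {
    abort(sprintf("outcome '%s': subgroup targets need a rule.", spec$name))
  }
  if (spec$measure == "binary") {
    vals <- c(overall, subgroup)
    if (any(vals <= 0 | vals >= 1)) {
      abort(sprintf("outcome '%s': binary targets are prevalences in (0, 1).", spec$name))
    }
  } else if (is.null(sd) || sd <= 0) {
    abort(sprintf("outcome '%s': continuous models need sd > 0.", spec$name))
  }
  structure(
    list(spec = spec, overall = as.numeric(overall),
         subgroup = if (!is.null(subgroup)) as.numeric(subgroup),
         rule = rule, sd = sd,
         missing_rate = rep_len(as.numeric(missing_rate), 2L)),
    class = "outcome_model"
  )
}

# Mean of a normal clipped (not truncated) to [lo, hi].
clipped_normal_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  lo * pnorm(a) + hi * pnorm(b, lower.tail = FALSE) +
    mu * (pnorm(b) - pnorm(a)) - sd * (dnorm(b) - dnorm(a))
}

solve_latent_mean <- function(target, sd, lo, hi) {
  if (target <= lo || target >= hi) {
    abort(sprintf("continuous target %.4g must lie strictly inside [%g, %g].",
                  target, lo, hi))
  }
  f <- function(mu) clipped_normal_mean(mu, sd, lo, hi) - target
  uniroot(f, lower = lo - 10 * sd, upper = hi + 10 * sd, tol = 1e-8)$root
}

#' Full stochastic specification of a synthetic survey
#'
#' Binds a schema, per-group sample sizes, covariate marginals,
#' calibrated outcome models and missingness rates. Covariates are drawn
#' independently unless a `dependence` hook ties one covariate's
#' conditional distribution to a parent covariate.
#'
#' @param schema A [survey_schema()].
#' @param n_per_group Length-2 integer: records in group 1 and group 2.
#' @param marginals Named list, one entry per covariate: a probability
#'   vector over its levels (shared by both groups) or a `levels x 2`
#'   matrix of per-group probabilities. Each column must sum to 1 (within
#'   1e-6; normalised).
#' @param models List of [outcome_model()]s covering every declared
#'   outcome.
#' @param missing_rates Named list of covariate missingness
#'   probabilities, scalar or per-group length 2. Omitted covariates are
#'   fully observed.
#' @param dependence Optional named list: for a covariate `child`, a list
#'   with `parent` (covariate name) and `prob`
#'   (`child levels x parent levels` conditional probability matrix).
#' @param seed Default seed used by [generate_survey()].
#' @return A `generator_config` with back-solved latent cell parameters.
#' @export
generator_config <- function(schema, n_per_group, marginals, models,
                             missing_rates = NULL, dependence = NULL,
                             seed = 1) {
  stopifnot(inherits(schema, "survey_schema"))
  if (length(n_per_group) != 2L || any(n_per_group < 1)) {
    abort("n_per_group must be two positive counts (group1, group2).")
  }
  marg <- lapply(names(schema$covariates), function(nm) {
    cv <- schema$covariates[[nm]]
    m <- marginals[[nm]]
    if (is.null(m)) abort(sprintf("no marginal declared for covariate '%s'.", nm))
    m <- if (is.matrix(m)) m else cbind(m, m)
    if (nrow(m) != length(cv$levels)) {
      abort(sprintf("marginal for '%s' must have one probability per level.", nm))
    }
    if (any(m < 0) || any(!is.finite(m))) {
      abort(sprintf("marginal for '%s': probabilities must be finite and >= 0.", nm))
    }
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-6)) {
      abort(sprintf("marginal for '%s' must sum to 1 per group (got %s).",
                    nm, paste(signif(cs, 6), collapse = ", ")))
    }
    sweep(m, 2, cs, "/")
  })
  names(marg) <- names(schema$covariates)

  if (!is.null(dependence)) {
    for (nm in names(dependence)) {
      dp <- dependence[[nm]]
      kc <- length(schema$covariates[[nm]]$levels)
      kp <- length(schema$covariates[[dp$parent]]$levels)
      if (!is.matrix(dp$prob) || nrow(dp$prob) != kc || ncol(dp$prob) != kp ||
          any(dp$prob < 0) || any(abs(colSums(dp$prob) - 1) > 1e-6)) {
        abort(sprintf("dependence for '%s': prob must be a %d x %d column-stochastic matrix.",
                      nm, kc, kp))
      }
    }
  }

  models <- check_schema_list2(models, "outcome_model")
  missing_out <- setdiff(names(schema$outcomes), names(models))
  if (length(missing_out)) {
    abort(sprintf("no outcome model for: %s", paste(missing_out, collapse = ", ")))
  }

  cfg <- structure(
    list(schema = schema, n_per_group = as.integer(n_per_group),
         marginals = marg, models = models,
         missing_rates = lapply(missing_rates %||% list(),
                                function(r) rep_len(as.numeric(r), 2L)),
         dependence = dependence, seed = as.integer(seed)),
    class = "generator_config"
  )
  cfg$latents <- lapply(models, function(mod) solve_model_cells(mod, cfg))
  cfg
}

check_schema_list2 <- function(x, cls) {
  if (!all(vapply(x, inherits, logical(1), cls))) {
    abort(sprintf("expected a list of %s objects.", cls))
  }
  names(x) <- vapply(x, function(m) m$spec$name, character(1))
  x
}

# Marginal probability of one condition under the configured marginals
# (after mixing over a dependence parent, if any).
condition_probability <- function(cond, cfg, group) {
  cv <- cfg$schema$covariates[[cond$covariate]]
  dp <- cfg$dependence[[cond$covariate]]
  p_lev <- if (is.null(dp)) {
    cfg$marginals[[cond$covariate]][, group]
  } else {
    as.numeric(dp$prob %*% cfg$marginals[[dp$parent]][, group])
  }
  thr <- match(cond$value[1], cv$levels)
  sel <- switch(cond$op,
    le = seq_along(cv$levels) <= thr,
    ge = seq_along(cv$levels) >= thr,
    `in` = seq_along(cv$levels) %in% match(cond$value, cv$levels))
  sum(p_lev[sel])
}

rule_probability <- function(rule, cfg, group) {
  covs <- vapply(rule$conditions, `[[`, character(1), "covariate")
  for (nm in covs) {
    dp <- cfg$dependence[[nm]]
    if (!is.null(dp) && dp$parent %in% covs) {
      abort("planted-rule covariates must be mutually independent under the configured marginals.")
    }
  }
  prod(vapply(rule$conditions, condition_probability, numeric(1), cfg, group))
}

# Back-solve latent cell parameters (2 groups x in/out of rule) so the
# observed cell summaries hit the model's targets.
solve_model_cells <- function(mod, cfg) {
  spec <- mod$spec
  if (is.null(mod$subgroup)) {
    p_in <- c(0, 0)
    cells_target <- cbind(out = mod$overall, inside = mod$overall)
  } else {
    for (cond in mod$rule$conditions) validate_condition(cond, cfg$schema)
    p_in <- vapply(1:2, function(g) rule_probability(mod$rule, cfg, g),
                   numeric(1))
    if (any(p_in <= 0 | p_in >= 1)) {
      abort(sprintf("outcome '%s': planted rule has degenerate probability %s.",
                    spec$name, paste(signif(p_in, 4), collapse = ", ")))
    }
    out_target <- (mod$overall - p_in * mod$subgroup) / (1 - p_in)
    cells_target <- cbind(out = out_target, inside = mod$subgroup)
  }
  latent <- if (spec$measure == "binary") {
    qlogis(cells_target)
  } else {
    apply(cells_target, c(1, 2), solve_latent_mean, sd = mod$sd,
          lo = spec$range[1], hi = spec$range[2])
  }
  list(latent = latent, cells_target = cells_target, p_in = p_in)
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> n = %d + %d (%s)\n", x$n_per_group[1],
              x$n_per_group[2],
              paste(x$schema$contrast_levels, collapse = " / ")))
  for (nm in names(x$models)) {
    mod <- x$models[[nm]]
    cat(sprintf("  %s [%s]: overall %s", nm, mod$spec$measure,
                paste(signif(mod$overall, 4), collapse = " / ")))
    if (!is.null(mod$subgroup)) {
      cat(sprintf("; planted %s -> %s", format(mod$rule),
                  paste(signif(mod$subgroup, 4), collapse = " / ")))
    }
    cat("\n")
  }
  invisible(x)
}

#' Generate a synthetic survey table
#'
#' Records are drawn independently: covariates from the configured
#' marginals (conditionally on a parent where a dependence hook is
#' declared), continuous outcomes as latent cell mean plus Gaussian noise
#' clipped to the declared range, binary outcomes as Bernoulli draws from
#' the latent cell logit. Missingness is applied last, independently at
#' the configured rates. Identical seeds give identical tables.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `survey_table`.
#' @export
generate_survey <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  schema <- config$schema
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  parts <- lapply(1:2, function(g) {
    n <- config$n_per_group[g]
    codes <- list()
    free <- setdiff(names(schema$covariates), names(config$dependence))
    for (nm in free) {
      codes[[nm]] <- sample.int(nrow(config$marginals[[nm]]), n,
                                replace = TRUE,
                                prob = config$marginals[[nm]][, g])
    }
    for (nm in names(config$dependence)) {
      dp <- config$dependence[[nm]]
      kc <- nrow(dp$prob)
      u <- runif(n)
      cum <- apply(dp$prob, 2, cumsum)
      pc <- codes[[dp$parent]]
      codes[[nm]] <- vapply(seq_len(n), function(i) {
        1L + findInterval(u[i], cum[-kc, pc[i]], left.open = FALSE)
      }, integer(1))
    }

    df <- tibble::as_tibble(lapply(schema$covariates, function(cv) {
      factor(cv$levels[codes[[cv$name]]], levels = cv$levels)
    }))
    df[[schema$contrast]] <- factor(schema$contrast_levels[g],
                                    levels = schema$contrast_levels)

    for (nm in names(config$models)) {
      mod <- config$models[[nm]]
      lat <- config$latents[[nm]]$latent
      inside <- if (is.null(mod$rule)) rep(FALSE, n) else {
        m <- rep(TRUE, n)
        for (cond in mod$rule$conditions) {
          cv <- schema$covariates[[cond$covariate]]
          thr <- match(cond$value[1], cv$levels)
          cd <- codes[[cond$covariate]]
          m <- m & switch(cond$op,
            le = cd <= thr,
            ge = cd >= thr,
            `in` = cd %in% match(cond$value, cv$levels))
        }
        m
      }
      eta <- ifelse(inside, lat[g, "inside"], lat[g, "out"])
      y <- if (mod$spec$measure == "binary") {
        rbinom(n, 1L, plogis(eta))
      } else {
        pmin(pmax(rnorm(n, eta, mod$sd), mod$spec$range[1]),
             mod$spec$range[2])
      }
      if (mod$missing_rate[g] > 0) y[runif(n) < mod$missing_rate[g]] <- NA
      df[[nm]] <- y
    }

    for (nm in names(config$missing_rates)) {
      r <- config$missing_rates[[nm]][g]
      if (r > 0) {
        v <- df[[nm]]
        v[runif(n) < r] <- NA
        df[[nm]] <- v
      }
    }
    df
  })

  data <- dplyr::bind_rows(parts)
  cols <- c(schema$contrast, names(schema$covariates), names(schema$outcomes))
  new_survey_table(data[cols], schema)
}

#' Zero out the planted interactions of a configuration
#'
#' Returns a configuration whose outcome gaps are homogeneous across all
#' subgroups (every cell uses the outside-rule parameters), the null
#' condition for type-I-error studies.
#'
#' @param config A [generator_config()].
#' @return A `generator_config` with no planted interactions.
#' @export
null_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  config$models <- lapply(config$models, function(mod) {
    mod$subgroup <- NULL
    mod$rule <- NULL
    mod
  })
  config$latents <- lapply(config$models, solve_model_cells, cfg = config)
  config
}
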