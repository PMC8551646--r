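# Internal search engine. Tables are prepared once into plain integer /
# numeric vectors so that the recursion and the permutation null (which
# re-runs the full search B times) stay cheap; the per-covariate split
# scoring itself is compiled (src/score_split.cpp). All tie-breaks are
# positional and therefore deterministic: candidates are enumerated in
# level order (ordinal thresholds) or bitmask order (nominal subsets),
# and the first minimum wins.

engine_prep <- function(table, outcome, covariates = NULL) {
  schema <- table_schema(table)
  spec <- resolve_outcome(schema, outcome)
  covs <- resolve_covariates(schema, covariates)
  g <- as.integer(table[[schema$contrast]]) - 1L   # 0 = reference group
  y <- as.numeric(table[[spec$name]])
  keep <- which(!is.na(y) & !is.na(g))
  if (!length(keep)) abort("no records with a non-missing outcome.")
  g <- g[keep]
  if (!any(g == 0L) || !any(g == 1L)) {
    abort("degenerate table: one contrast group is empty.")
  }
  list(
    y = y[keep],
    g = g,
    n = length(keep),
    codes = lapply(covs, function(cv) as.integer(table[[cv$name]])[keep]),
    covs = covs,
    binary = spec$measure == "binary",
    sign = spec$disadvantage_sign,
    spec = spec,
    schema = schema
  )
}

engine_offset <- function(prep, g = prep$g) {
  m1 <- mean(prep$y[g == 0L])
  m2 <- mean(prep$y[g == 1L])
  prep$sign * (m2 - m1)
}

# Best admissible split of covariate j at node idx, or NULL if the
# covariate is unusable there (single observed level / nothing
# admissible). `g` overrides the contrast labels (permutation null).
score_covariate <- function(prep, idx, j, D, min_node, min_events,
                            g = prep$g, adjust = sidak_adjust) {
  cv <- prep$covs[[j]]
  x <- prep$codes[[j]]
  res <- score_split_cpp(idx, x, prep$y, g, length(cv$levels),
                         cv$kind == "ordinal", prep$binary, prep$sign, D,
                         min_node, min_events)
  if (is.null(res)) return(NULL)

  if (cv$kind == "ordinal") {
    thr <- res$side[1]
    in1 <- !is.na(x[idx]) & x[idx] <= thr
    cond <- if (res$promoted1) {
      condition(cv$name, "le", cv$levels[thr])
    } else {
      condition(cv$name, "ge", cv$levels[thr + 1L])
    }
  } else {
    in1 <- !is.na(x[idx]) & x[idx] %in% res$side
    cond <- if (res$promoted1) {
      condition(cv$name, "in", cv$levels[res$side])
    } else {
      condition(cv$name, "in", cv$levels[setdiff(res$obs, res$side)])
    }
  }

  list(
    j = j, covariate = cv$name,
    p = res$p, ncand = res$ncand,
    p_adj = adjust(res$p, res$ncand),
    z1 = res$z1, z2 = res$z2,
    z = max(res$z1, res$z2),
    cond = cond,
    idx = idx[if (res$promoted1) in1 else !in1],
    n1 = res$n1, n2 = res$n2, m1 = res$m1, m2 = res$m2, se = res$se,
    n_per_arm = setNames(res$n_per_arm, c("n11", "n12", "n21", "n22"))
  )
}

sidak_adjust <- function(p, ncand) pmin(1, 1 - (1 - p)^ncand)

# Rank usable covariates at a node by multiplicity-adjusted best-split p,
# truncated to the best M. `avail` indexes prep$covs; schema declaration
# order breaks ties because order() is stable.
rank_node <- function(prep, idx, avail, D, cfg, g = prep$g) {
  cands <- vector("list", length(avail))
  k <- 0L
  adjust <- cfg$adjust %||% sidak_adjust
  for (j in avail) {
    sc <- score_covariate(prep, idx, j, D, cfg$min_node, cfg$min_events,
                          g = g, adjust = adjust)
    if (!is.null(sc)) {
      k <- k + 1L
      cands[[k]] <- sc
    }
  }
  if (k == 0L) return(list())
  cands <- cands[seq_len(k)]
  ord <- order(vapply(cands, `[[`, numeric(1), "p_adj"))
  cands[ord[seq_len(min(cfg$M, k))]]
}

# Full recursive search. Returns a list of promising-node records; the
# caller formats them. Identical rules reached along different search
# paths are merged, keeping the smallest creating p.
sides_engine <- function(prep, cfg, D, g = prep$g) {
  acc <- new.env(parent = emptyenv())
  acc$nodes <- list()
  schema <- prep$schema

  walk <- function(idx, avail, parent_p, depth, conds) {
    for (e in rank_node(prep, idx, avail, D, cfg, g = g)) {
      if (e$p_adj <= cfg$gamma[depth + 1L] * parent_p) {
        rule <- subgroup_rule(c(conds, list(e$cond)))
        key <- rule_key(rule, schema)
        rec <- acc$nodes[[key]]
        if (is.null(rec) || e$p_adj < rec$p) {
          acc$nodes[[key]] <- list(
            rule = rule, depth = depth + 1L, p = e$p_adj, p_raw = e$p,
            ncand = e$ncand, z = e$z,
            n1 = e$n1, n2 = e$n2, m1 = e$m1, m2 = e$m2, se = e$se
          )
        }
        if (depth + 1L < cfg$L) {
          walk(e$idx, setdiff(avail, e$j), e$p_adj, depth + 1L,
               c(conds, list(e$cond)))
        }
      }
    }
  }

  walk(seq_len(prep$n), seq_along(prep$covs), 1, 0L, list())
  unname(acc$nodes)
}
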