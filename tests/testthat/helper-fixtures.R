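# Fixtures are built in code; nothing is stored on disk.

# Minimal schema: one ordinal + one nominal covariate, one continuous and
# one binary outcome, contrast a/b with a as reference.
tiny_schema <- function() {
  survey_schema(
    contrast = "grp",
    contrast_levels = c("a", "b"),
    covariates = list(
      covariate_schema("grade", "ordinal", c("5", "7", "9", "11")),
      covariate_schema("colour", "nominal", c("red", "green", "blue"),
                       missing_label = "Missing")
    ),
    outcomes = list(
      outcome_spec("score", "continuous", range = c(-100, 100)),
      outcome_spec("event", "binary")
    )
  )
}

# p binary nominal covariates, one continuous outcome; used by the
# exhaustive-search oracle tests.
bin_schema <- function(p = 3) {
  survey_schema(
    contrast = "grp",
    contrast_levels = c("a", "b"),
    covariates = lapply(paste0("c", seq_len(p)), function(nm) {
      covariate_schema(nm, "nominal", c("A", "B"))
    }),
    outcomes = list(outcome_spec("score", "continuous", range = c(-1e6, 1e6)))
  )
}

random_bin_table <- function(n = 400, p = 3, seed = 1, effect = NULL) {
  withr::with_seed(seed, {
    df <- as.data.frame(lapply(seq_len(p), function(j) {
      sample(c("A", "B"), n, replace = TRUE)
    }))
    names(df) <- paste0("c", seq_len(p))
    df$grp <- sample(c("a", "b"), n, replace = TRUE)
    mu <- 1 * (df$grp == "b")
    if (!is.null(effect)) mu <- mu + effect(df) * (df$grp == "b")
    df$score <- rnorm(n, mu, 1)
    survey_table(df, bin_schema(p))
  })
}

# Direct two-group stats on a data frame subset; independent of the
# package's effect code paths beyond base arithmetic.
raw_diff <- function(df, sign = 1) {
  y1 <- df$score[df$grp == "a"]
  y2 <- df$score[df$grp == "b"]
  d <- sign * (mean(y2) - mean(y1))
  se <- sqrt(var(y1) / length(y1) + var(y2) / length(y2))
  list(diff = d, se = se, n1 = length(y1), n2 = length(y2))
}

# Exhaustive oracle for binary covariates at depth <= 2: enumerate every
# rule directly with data-frame arithmetic and apply the identical
# criterion, promising-child choice and continuation rule.
oracle_exhaustive <- function(tab, cfg) {
  df <- as.data.frame(tab)
  p <- sum(startsWith(names(df), "c"))
  D <- raw_diff(df)$diff
  score_cov <- function(sub, j) {
    cv <- paste0("c", j)
    a <- sub[sub[[cv]] == "A", ]
    b <- sub[sub[[cv]] == "B", ]
    cnt <- function(d) min(sum(d$grp == "a"), sum(d$grp == "b"))
    if (min(cnt(a), cnt(b)) < cfg$min_node) return(NULL)
    za <- with(raw_diff(a), (diff - D) / se)
    zb <- with(raw_diff(b), (diff - D) / se)
    if (!is.finite(za) || !is.finite(zb)) return(NULL)
    list(p = min(1, 2 * pnorm(max(za, zb), lower.tail = FALSE)),
         side = if (za >= zb) "A" else "B", j = j)
  }
  found <- list()
  note <- function(key, p) {
    if (is.null(found[[key]]) || p < found[[key]]) found[[key]] <<- p
  }
  d1 <- list()
  for (j in seq_len(p)) {
    s <- score_cov(df, j)
    if (!is.null(s) && s$p <= cfg$gamma[1]) {             # root parent p = 1
      note(sprintf("c%d:%s", j, s$side), s$p)
      d1[[length(d1) + 1L]] <- s
    }
  }
  if (cfg$L >= 2) {
    for (s in d1) {
      sub <- df[df[[paste0("c", s$j)]] == s$side, ]
      for (k in setdiff(seq_len(p), s$j)) {
        s2 <- score_cov(sub, k)
        if (!is.null(s2) && s2$p <= cfg$gamma[2] * s$p) {
          key <- paste(sort(c(sprintf("c%d:%s", s$j, s$side),
                              sprintf("c%d:%s", k, s2$side))),
                       collapse = " & ")
          note(key, s2$p)
        }
      }
    }
  }
  found
}
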