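---
title: "Searching for social locations with amplified group differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching for social locations with amplified group differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sidesearch)
set_log_level("quiet")
```

## The problem

Adolescent males and females report systematically different mental
health: in large school-based surveys, males report higher positive
psychosomatic health scores and lower prevalences of depressive symptoms
and diagnosed mental illness. Intersectionality theory predicts that
such gaps are not uniform: they concentrate in *social locations* —
intersections of social and demographic characteristics such as "older
adolescents of low family affluence". `sidesearch` implements a
data-mining approach to find such locations: a differential-effect
variant of recursive partitioning (SIDES — Subgroup Identification based
on Differential Effect Search), with the gender contrast playing the
role of the "treatment" whose effect varies across subgroups.

Unlike classification trees, the search does not partition the sample
into homogeneous cells. It hunts for (possibly overlapping) subgroups
where the between-group difference is *significantly larger than in the
whole population*, and controls the search's selection effects with a
permutation-based adjustment.

## The model and the statistics

Let the contrast take values in two groups (reference group 1, e.g.
males), and let $X$ be an outcome: either a bounded continuous score or
a binary indicator. For any subgroup $S$, the gap is the signed
difference

$$\hat\Delta_S = s \cdot \left(\bar X_{2,S} - \bar X_{1,S}\right),$$

where $s \in \{+1, -1\}$ is the outcome's *disadvantage sign*, chosen so
that the inequality of interest is positive (for a positively-coded
score on which the reference group scores higher, $s = -1$). Its
standard error is the unpooled (Welch-type) form for means,
$\sqrt{s_1^2/n_1 + s_2^2/n_2}$, or the standard unpooled binomial form
for proportions. 95% intervals use a fixed multiplier of 1.96.

Directly testing $\hat\Delta_S > 0$ is useless here: the overall gap is
itself large and highly significant, so every sizeable subgroup carries
an enormous z-statistic (and its p-value underflows). The search
therefore *centers* each subgroup statistic at the whole-sample gap
$D = \hat\Delta_{\text{all}}$, computed once on the full table and held
fixed through the recursion:

$$Z_S = \frac{\hat\Delta_S - D}{\widehat{SE}(\hat\Delta_S)}.$$

$Z_S$ tests for an *excess* inequality over the population-wide one.
The full sample scores exactly zero against its own offset, and for
small subgroups of a homogeneous population $Z_S$ is approximately
standard normal. (Two caveats the test suite makes explicit: because $D$
is estimated from the same data, a subgroup holding a fraction $f$ of
the sample has variance roughly $1 - f$, and subgroups drawn from one
dataset are mutually correlated. The normal reference is the
small-subgroup regime.)

A candidate binary split of a node produces children with statistics
$Z_1, Z_2$ and is scored by

$$p_{\text{split}} = 2 \cdot \min\{1 - \Phi(Z_1),\; 1 - \Phi(Z_2)\},$$

capped at 1. Minimising $p_{\text{split}}$ over a covariate's candidate
partitions finds the bipartition whose better child shows the most
pronounced excess gap; the larger-$Z$ child is the *promising* child
carried forward. Note the one-sidedness: as $Z_1 \to -\infty$ the
criterion tends to $2(1 - \Phi(Z_2))$, and it vanishes only when *some*
child has a large positive excess.

## The search

At each node the algorithm:

1. enumerates candidate bipartitions per covariate — the $k - 1$
   order-respecting thresholds of an ordinal covariate with $k$ observed
   levels, or the $2^{k-1} - 1$ subset bipartitions of a nominal one
   (nominal covariates with more than 12 observed levels are rejected
   rather than enumerated);
2. drops inadmissible candidates: each child must keep at least
   `min_node` records per contrast group (default 30) and, for binary
   outcomes, at least `min_events` events per arm (default 5, guarding
   the normal approximation);
3. takes each covariate's best candidate and adjusts it for the number
   of admissible candidates with a Šidák correction
   $1 - (1 - p)^{n_{\text{cand}}}$, removing the advantage of
   many-levelled covariates; the adjustment form is pluggable, as the
   literature admits several;
4. ranks covariates by adjusted p (ties broken by schema declaration
   order, making runs deterministic) and keeps the best `M = 5`;
5. for each retained covariate, admits the promising child as a
   *promising subgroup* if it passes the continuation (complexity)
   criterion $p_{\text{child}} \le \gamma_l \, p_{\text{parent}}$, and
   recurses inside it, never reusing a covariate along one path and
   stopping at rule depth `L = 3`. The root's parent p is defined as 1,
   so first-level children are judged on their own criterion; the
   per-level multipliers $\gamma_l$ default to 1 (a child must be at
   least as significant as its parent).

Rules reached along different orders (grade then affluence vs. affluence
then grade) describe the same subgroup; they are de-duplicated on a
canonical key (sorted conditions; nominal subsets represented by the
smaller side of the bipartition), keeping the smallest creating p. The
output is a set of possibly overlapping subgroup rules such as
`grade>=9 & affluence in {Low}`.

### Multiplicity control

The search optimises over thousands of candidate rules, so even under a
homogeneous gap some node will show a small criterion p. The adjustment
re-runs the *entire search* on `B` datasets in which the contrast labels
are permuted uniformly over all records — the strongest exchangeable
null for "no subgroup carries an excess gap" — recomputing $D$ on each
permuted dataset, and records the minimal criterion p each null search
attains (1 if none). A subgroup's adjusted p-value is the add-one
permutation tail
$(1 + \#\{b : \min p_b \le p_{\text{obs}}\}) / (B + 1)$, bounded below
by $1/(B+1)$. `B` defaults to 1000; the test suite uses 99 for speed.
The permutation scheme is unstratified because the emulated survey
publishes no clustering variable to stratify on.

## The synthetic cohort

The restricted survey microdata behind analyses of this kind cannot be
redistributed, so the package ships a generator
(`default_survey_config()`) that emulates a 2017-18 Canadian
adolescent-survey cohort of 10,349 males and 10,872 females aged 11-15:

* **Covariates.** Eight social locations — school grade (five ordered
  level groups), urban/rural size class, family-SES quintile, family
  structure, years in Canada, relative affluence, religious involvement,
  racial/cultural background — drawn independently per record from
  per-gender marginals matching the published descriptive table, with
  per-gender missingness at the published rates (e.g. 20.7% of male SES
  values). Independence of covariates is a simplification (the real
  joint distribution is unpublished); an optional dependence hook can
  tie one covariate's conditional distribution to a parent covariate for
  stress tests.
* **Outcomes.** A continuous positive psychosomatic health score
  (Gaussian noise, residual sd 6.5 score points, clipped to the declared
  range) and two binary outcomes (depressive symptoms, diagnosed mental
  illness) drawn from per-cell Bernoulli probabilities.
* **Planted ground truth.** All three outcome models carry a
  gender-by-subgroup interaction on the rule
  `grade>=9 & affluence>=Low` ("older adolescents of low affluence"),
  calibrated so the observed summaries reproduce the published values:
  overall gaps of 3.7 score points, 17.6 and 6.6 percentage points, and
  subgroup gaps of 5.0, 24.3 and 12.6.

Calibration is exact by construction. Binary cell logits are
`qlogis(target)`. Continuous cell means are found by numerically
inverting the clipped-normal mean (`uniroot`, tolerance $10^{-8}$),
since clipping at the range boundary would otherwise bias the means
downward; out-of-rule cell targets are back-solved from the overall
targets and the rule probability under the configured marginals, so the
overall mixture is exact.

Two calibration choices deserve a flag. First, the psychosomatic score
is nominally an eight-item 0-32 sum, but the published per-group means
(32.9 for males overall) exceed 32; since no mean inside [0, 32] can
reproduce them, the default outcome spec admits [0, 40] and treats the
printed summaries as the calibration truth. The range is configurable
for data that truly live on 0-32. Second, the published subgroup
confidence intervals imply a subgroup of roughly 1,400-3,500
respondents, whereas independent marginals with published missingness
yield about 680; the generator matches the published *cell summaries*,
not the unpublished joint distribution, so permutation-adjusted
significance of the planted subgroup at full cohort size is weaker here
than in the source analysis. Recovery of the rule itself (below) is
unaffected.

### What the generator does and does not establish

Passing tests on this synthetic cohort show that the pipeline finds
planted excess-gap intersections under realistic marginals, missingness
and effect sizes, and that its false-positive rate is controlled under a
homogeneous gap. They do not certify behaviour under features the
generator omits: school-level clustering, survey design weights,
correlated covariates, informative missingness, or non-Gaussian score
noise.

## Operating characteristics checked by the test suite

* **Exactness.** Split criterion vs. an independent error-function
  oracle to $10^{-12}$; `best_split` and the full recursion vs.
  brute-force enumeration on small problems; centered z of the full
  sample exactly 0.
* **Type-I error.** 200 homogeneous-gap datasets of n = 4,000 at the
  cohort gender ratio, B = 99 permutations: the share of datasets with
  any adjusted p below 0.05 must stay within binomial slack
  ($\le 0.081$) of the nominal level. The sizes keep the check inside a
  routine test run; the statistic is size-calibrated, so the rate, not
  its Monte-Carlo precision, is what the scaled-down study verifies.
* **Recovery.** 50 datasets of n = 20,000 with the default planted
  intersection. A dataset counts as recovered when the search reports a
  promising subgroup containing both planted conditions for at least one
  of the three outcomes — the planted location carries an excess gap on
  all three, mirroring a study design in which a location matters when
  any outcome flags it; the required rate is 80%. Per-outcome recovery
  is lower (roughly 60-76%), the binding step being the exact grade
  threshold: diluted neighbours (`grade>=8`, `grade>=10 and 11`) are
  frequent near-winners at this effect size.
* **Calibration.** Simulated overall summaries at full cohort size match
  the published values within three Monte-Carlo standard errors;
  marginals pass chi-square goodness of fit at n = 100,000.

## Numerical and design notes

* Candidate children with zero standard error (constant outcome) are
  inadmissible; their z is set to $-\infty$ so they can never be the
  promising side. Criterion p-values are floored at the smallest
  positive double instead of underflowing to zero.
* All tie-breaks are positional: thresholds are enumerated in level
  order, nominal subsets in bitmask order, `which.min` takes the first
  minimum, and covariate ranking ties follow schema declaration order.
  Two runs with the same inputs and seeds are identical.
* Records missing a value on a split covariate belong to neither child
  (complete-case per split) — the emulated study reports missingness but
  not its handling inside the search, so this is a package choice,
  surfaced in the data-model documentation.
* The per-covariate split scoring is compiled (C++ via Rcpp); the
  permutation null re-runs the full search `B` times per fit, and a
  pure-R inner loop would dominate the run time of simulation studies.
* Randomness enters only through data generation and label permutation;
  each takes an explicit integer seed, and derived seeds stay below
  $2^{31}$.

## A worked run

```{r example, fig.width = 7, fig.height = 4}
cfg <- default_survey_config(n_per_group = c(4900, 5100))
tab <- generate_survey(cfg, seed = 7)

glance(group_effect(tab, "diagnosis"))

fit <- sides(tab, "diagnosis", config = sides_config(B = 199, seed = 8))
glance(fit)
head(dplyr::select(tidy(fit), rule, n1, n2, diff, ci_low, ci_high,
                   adjusted_p))
autoplot(fit)
```

The forest plot shows each discovered subgroup's gap with its 95%
interval against the overall gap (dashed line). At this reduced sample
size the planted intersection is usually reported among the promising
subgroups; its adjusted p-value reflects how often a label-permuted
search produces an equally extreme node anywhere in the rule space.

## Limitations

* Survey design (weights, school clustering) is out of scope; estimates
  and standard errors treat records as independent.
* Missing covariate values are neither imputed nor modelled.
* The Šidák per-covariate adjustment is a stand-in for the original
  algorithm's correlation-adjusted version, which is not published in
  reusable form.
* Honest effect re-estimation on held-out data (to counter the winner's
  curse in reported subgroup gaps) is not implemented; reported subgroup
  estimates are selection-biased upward by construction.
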